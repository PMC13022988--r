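#' Construct a topology
#'
#' A topology is an ordered table of atom records carrying the metadata
#' needed by every downstream selection: atom name, element, residue
#' name/number and chain. Coordinates live in the trajectory, not here.
#'
#' @param atoms data.frame with columns `serial` (positive integer),
#'   `name` (short atom name, e.g. "CA"), `element` (chemical symbol),
#'   `resname` (residue name), `resid` (author residue number), `chain`
#'   (single character), `occupancy` and `bfactor` (numeric pass-through).
#' @return An object of class `topology`.
#' @export
topology <- function(atoms) {
  required <- c("serial", "name", "element", "resname", "resid", "chain",
                "occupancy", "bfactor")
  missing <- setdiff(required, names(atoms))
  if (length(missing) > 0)
    stop("topology atoms table lacks columns: ", paste(missing, collapse = ", "))
  if (nrow(atoms) < 1) stop("a topology needs at least one atom")
  if (any(!nzchar(atoms$element)))
    stop("every atom needs a non-empty element symbol")
  key <- paste(atoms$chain, atoms$resid, atoms$name)
  if (anyDuplicated(key))
    warning("duplicate (chain, resid, name) atom keys in topology")
  atoms$serial <- as.integer(atoms$serial)
  atoms$resid <- as.integer(atoms$resid)
  rownames(atoms) <- NULL
  structure(list(atoms = atoms), class = "topology")
}

#' @export
print.topology <- function(x, ...) {
  a <- x$atoms
  cat(sprintf("topology: %d atoms, %d residues, chains [%s]\n",
              nrow(a), length(unique(paste(a$chain, a$resid))),
              paste(unique(a$chain), collapse = " ")))
  invisible(x)
}

#' Number of atoms in a topology
#' @param top topology
#' @return integer atom count
#' @export
n_atoms <- function(top) nrow(top$atoms)

WATER_RESNAMES <- c("HOH", "WAT", "TIP3", "SOL", "TIP")
BACKBONE_NAMES <- c("N", "CA", "C", "O")

#' Logical atom masks derived from a topology
#'
#' `mask_heavy()` selects non-hydrogen atoms, `mask_backbone()` the
#' protein backbone by atom name (N, CA, C, O; water oxygens are
#' excluded even though they are named "O"-like), and `mask_water()`
#' atoms of the common water residue names (HOH, WAT, TIP3, SOL, TIP).
#'
#' @param top topology
#' @return logical vector over atoms
#' @export
mask_heavy <- function(top) top$atoms$element != "H"

#' @rdname mask_heavy
#' @export
mask_water <- function(top) top$atoms$resname %in% WATER_RESNAMES

#' @rdname mask_heavy
#' @export
mask_backbone <- function(top) {
  top$atoms$name %in% BACKBONE_NAMES & !mask_water(top)
}

#' Construct an atom selection
#'
#' @param indices strictly increasing 1-based atom indices into a topology
#' @param label descriptive label
#' @param top optional topology used to range-check the indices
#' @return object of class `selection`
#' @export
selection <- function(indices, label = "", top = NULL) {
  indices <- as.integer(indices)
  if (length(indices) == 0) stop("empty selection")
  if (is.unsorted(indices, strictly = TRUE))
    stop("selection indices must be strictly increasing")
  if (indices[1] < 1) stop("selection indices are 1-based")
  if (!is.null(top) && indices[length(indices)] > n_atoms(top))
    stop("selection index exceeds topology size")
  structure(list(indices = indices, label = label), class = "selection")
}

#' @export
print.selection <- function(x, ...) {
  cat(sprintf("selection '%s': %d atoms\n", x$label, length(x$indices)))
  invisible(x)
}

#' Select atoms with a small query language
#'
#' Queries are conjunctions of clauses joined by `and`:
#' \describe{
#'   \item{`backbone`, `heavy`, `water`}{the derived masks}
#'   \item{`protein`}{non-water residues}
#'   \item{`resid A..B` or `resid N`}{residue-number range or single residue}
#'   \item{`resname X`}{residue name}
#'   \item{`name X`}{atom name}
#'   \item{`chain X`}{chain identifier}
#' }
#' For example `"resname HIS and heavy"` selects the heavy atoms of all
#' histidine residues.
#'
#' @param top topology
#' @param query query string
#' @return a [selection()]
#' @export
select_atoms <- function(top, query) {
  clauses <- strsplit(trimws(query), "\\s+and\\s+")[[1]]
  keep <- rep(TRUE, n_atoms(top))
  for (cl in clauses) {
    tok <- strsplit(trimws(cl), "\\s+")[[1]]
    kw <- tolower(tok[1])
    m <- switch(kw,
      backbone = mask_backbone(top),
      heavy = mask_heavy(top),
      water = mask_water(top),
      protein = !mask_water(top),
      resid = {
        if (length(tok) != 2) stop("resid clause needs one argument: ", cl)
        if (grepl("\\.\\.", tok[2])) {
          ab <- as.integer(strsplit(tok[2], "\\.\\.")[[1]])
          top$atoms$resid >= ab[1] & top$atoms$resid <= ab[2]
        } else top$atoms$resid == as.integer(tok[2])
      },
      resname = {
        if (length(tok) != 2) stop("resname clause needs one argument: ", cl)
        top$atoms$resname == tok[2]
      },
      name = {
        if (length(tok) != 2) stop("name clause needs one argument: ", cl)
        top$atoms$name == tok[2]
      },
      chain = {
        if (length(tok) != 2) stop("chain clause needs one argument: ", cl)
        top$atoms$chain == tok[2]
      },
      stop("unknown selection clause: ", cl)
    )
    keep <- keep & m
  }
  if (!any(keep)) stop("selection '", query, "' matches no atoms")
  selection(which(keep), label = query, top = top)
}

#' Construct a trajectory
#'
#' @param top topology
#' @param coords numeric array of dimension n_frames x n_atoms x 3, in
#'   Angstrom
#' @param frame_interval time between saved frames, in ns (> 0)
#' @param condition_label experimental condition (e.g. "protonated")
#' @param replicate_id replicate identifier
#' @param aligned logical; set by [align_trajectory()], required by
#'   analyses that assume superposed frames
#' @return object of class `trajectory`
#' @export
trajectory <- function(top, coords, frame_interval,
                       condition_label = "", replicate_id = "",
                       aligned = FALSE) {
  if (length(dim(coords)) != 3 || dim(coords)[3] != 3)
    stop("coords must be an n_frames x n_atoms x 3 array")
  if (dim(coords)[2] != n_atoms(top))
    stop("coords atom dimension (", dim(coords)[2],
         ") does not match topology (", n_atoms(top), ")")
  if (!all(is.finite(coords))) stop("coords contain non-finite values")
  if (!is.numeric(frame_interval) || frame_interval <= 0)
    stop("frame_interval must be a positive time in ns")
  structure(list(topology = top, coords = coords,
                 frame_interval = frame_interval,
                 condition_label = condition_label,
                 replicate_id = replicate_id,
                 aligned = isTRUE(aligned)),
            class = "trajectory")
}

#' @export
print.trajectory <- function(x, ...) {
  cat(sprintf(
    "trajectory: %d frames x %d atoms, %.4g ns/frame%s%s%s\n",
    n_frames(x), n_atoms(x$topology), x$frame_interval,
    if (nzchar(x$condition_label)) paste0(", condition=", x$condition_label) else "",
    if (nzchar(x$replicate_id)) paste0(", replicate=", x$replicate_id) else "",
    if (x$aligned) ", aligned" else ""))
  invisible(x)
}

#' Number of frames in a trajectory
#' @param traj trajectory
#' @return integer frame count
#' @export
n_frames <- function(traj) dim(traj$coords)[1]

#' Frame times of a trajectory
#'
#' Frame f (1-based) is at time (f - 1) * frame_interval ns, i.e. the
#' first saved frame defines t = 0.
#'
#' @param traj trajectory
#' @return numeric vector of times in ns
#' @export
frame_times <- function(traj) (seq_len(n_frames(traj)) - 1) * traj$frame_interval

#' Extract one frame's coordinates
#' @param traj trajectory
#' @param f 1-based frame index
#' @return n_atoms x 3 matrix
#' @export
frame_coords <- function(traj, f) {
  if (f < 1 || f > n_frames(traj)) stop("frame index out of range")
  matrix(traj$coords[f, , ], ncol = 3)
}

#' Parse a length with an optional unit suffix
#'
#' Configuration values may carry an "A"/"Angstrom" or "nm" suffix
#' (e.g. "3.5A", "1nm"); bare numbers are taken as Angstrom, the
#' package-wide internal unit. nm values are converted (1 nm = 10 A).
#'
#' @param x numeric, or string like "10", "3.5A", "1nm"
#' @return length in Angstrom
#' @export
parse_length <- function(x) {
  if (is.numeric(x)) return(x)
  s <- trimws(tolower(as.character(x)))
  m <- regmatches(s, regexec("^([0-9eE.+-]+)\\s*(nm|angstrom|a|)$", s))[[1]]
  if (length(m) == 0 || is.na(suppressWarnings(as.numeric(m[2]))))
    stop("cannot parse length: ", x)
  val <- as.numeric(m[2])
  if (m[3] == "nm") val * 10 else val
}
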