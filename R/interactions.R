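# Ligand-residue contact statistics.
#
# A contact exists in a frame when the minimum ligand:residue heavy-atom
# distance is strictly below the cutoff (default 3.5 Angstrom). A residue
# is "significant" when its contact fraction reaches at least 10% of
# frames in either condition. Both conventions are deliberate about ties:
# strict "<" at the distance cutoff, inclusive ">=" at the fraction
# threshold. Hydrogens are excluded by element, never by name prefix.

heavy_subset <- function(top, sel) {
  idx <- sel_indices(sel)
  idx[top$atoms$element[idx] != "H"]
}

#' List the residues of a topology
#'
#' @param top topology
#' @param exclude_water drop water residues
#' @return data.frame with `chain`, `resid`, `resname` per residue, in
#'   residue-number order
#' @export
residue_list <- function(top, exclude_water = TRUE) {
  a <- top$atoms
  if (exclude_water) a <- a[!mask_water(top), , drop = FALSE]
  key <- !duplicated(paste(a$chain, a$resid))
  out <- a[key, c("chain", "resid", "resname"), drop = FALSE]
  out <- out[order(out$chain, out$resid), , drop = FALSE]
  rownames(out) <- NULL
  out
}

residue_atom_indices <- function(top, chain, resid) {
  which(top$atoms$chain == chain & top$atoms$resid == resid)
}

#' Minimum heavy-atom distance between a ligand and one residue
#'
#' @param frame n_atoms x 3 coordinate matrix
#' @param top topology
#' @param ligand_sel ligand selection (restricted to heavy atoms here)
#' @param residue one row of [residue_list()] (or a list with `chain`,
#'   `resid`)
#' @return minimum Euclidean distance in Angstrom over all ligand x
#'   residue heavy-atom pairs
#' @export
min_heavy_distance <- function(frame, top, ligand_sel, residue) {
  li <- heavy_subset(top, ligand_sel)
  ri <- residue_atom_indices(top, residue$chain, residue$resid)
  ri <- ri[top$atoms$element[ri] != "H"]
  if (length(li) == 0) stop("ligand selection has no heavy atoms")
  if (length(ri) == 0)
    stop("residue ", residue$resid, " has no heavy atoms")
  L <- frame[li, , drop = FALSE]
  R <- frame[ri, , drop = FALSE]
  # |l - r|^2 = |l|^2 + |r|^2 - 2 l.r, minimized over all pairs
  d2 <- outer(rowSums(L^2), rowSums(R^2), `+`) - 2 * tcrossprod(L, R)
  sqrt(max(min(d2), 0))
}

min_dist_series <- function(traj, ligand_idx, res_idx) {
  nf <- n_frames(traj)
  out <- numeric(nf)
  for (f in seq_len(nf)) {
    L <- matrix(traj$coords[f, ligand_idx, ], ncol = 3)
    R <- matrix(traj$coords[f, res_idx, ], ncol = 3)
    d2 <- outer(rowSums(L^2), rowSums(R^2), `+`) - 2 * tcrossprod(L, R)
    out[f] <- sqrt(max(min(d2), 0))
  }
  out
}

#' Per-residue contact fractions for one replicate
#'
#' For each residue, the fraction of frames in which the minimum
#' ligand:residue heavy-atom distance is strictly less than `cutoff`.
#'
#' @param traj aligned [trajectory()]
#' @param ligand_sel ligand selection
#' @param residues data.frame as from [residue_list()]; defaults to all
#'   non-water residues not overlapping the ligand
#' @param cutoff contact distance in Angstrom (accepts "3.5A"/"0.35nm")
#' @return named numeric vector of contact fractions in [0, 1], names
#'   "chain:resid:resname"
#' @export
contact_frequencies <- function(traj, ligand_sel,
                                residues = NULL, cutoff = 3.5) {
  cutoff <- parse_length(cutoff)
  if (cutoff <= 0) stop("cutoff must be positive")
  top <- traj$topology
  li <- heavy_subset(top, ligand_sel)
  if (length(li) == 0) stop("ligand selection has no heavy atoms")
  if (is.null(residues)) {
    residues <- residue_list(top)
    lig_res <- unique(paste(top$atoms$chain[li], top$atoms$resid[li]))
    residues <- residues[!paste(residues$chain, residues$resid) %in% lig_res, ,
                         drop = FALSE]
  }
  fr <- numeric(nrow(residues))
  for (i in seq_len(nrow(residues))) {
    ri <- residue_atom_indices(top, residues$chain[i], residues$resid[i])
    ri <- ri[top$atoms$element[ri] != "H"]
    if (length(ri) == 0)
      stop("residue ", residues$resid[i], " has no heavy atoms")
    d <- min_dist_series(traj, li, ri)
    fr[i] <- mean(d < cutoff)
  }
  names(fr) <- paste(residues$chain, residues$resid, residues$resname,
                     sep = ":")
  fr
}

#' Assemble a contact table over replicates
#'
#' @param fraction_list list of named fraction vectors (one per
#'   replicate, as from [contact_frequencies()]; all on the same residue
#'   set)
#' @param n_frames_per_rep integer vector of frame counts per replicate
#'   (weights for pooled fractions)
#' @param condition_label condition name
#' @return object of class `contact_table`: residue x replicate fraction
#'   matrix plus per-replicate frame counts
#' @export
contact_table <- function(fraction_list, n_frames_per_rep,
                          condition_label = "") {
  if (length(fraction_list) != length(n_frames_per_rep))
    stop("one frame count per replicate is required")
  keys <- names(fraction_list[[1]])
  for (fr in fraction_list)
    if (!identical(names(fr), keys))
      stop("replicates disagree on the residue set")
  m <- do.call(cbind, fraction_list)
  colnames(m) <- paste0("rep", seq_along(fraction_list))
  if (any(m < 0 | m > 1)) stop("contact fractions must lie in [0, 1]")
  structure(list(fractions = m,
                 n_frames = as.integer(n_frames_per_rep),
                 condition_label = condition_label),
            class = "contact_table")
}

#' @export
print.contact_table <- function(x, ...) {
  cat(sprintf("contact table '%s': %d residues x %d replicates\n",
              x$condition_label, nrow(x$fractions), ncol(x$fractions)))
  invisible(x)
}

pooled_fractions <- function(tab) {
  w <- tab$n_frames / sum(tab$n_frames)
  as.numeric(tab$fractions %*% w)
}

#' Significant contact residues across two conditions
#'
#' A residue is significant when its contact fraction reaches at least
#' `threshold` (default 10% of frames) in either condition. By default
#' fractions are pooled over replicates with frame-count weights
#' (replicates of unequal length contribute proportionally); with
#' `mode = "any_replicate"` a single replicate reaching the threshold
#' suffices.
#'
#' @param table_a,table_b [contact_table()]s for the two conditions, on a
#'   shared residue universe
#' @param threshold fraction in (0, 1]
#' @param mode "pooled" (default) or "any_replicate"
#' @return character vector of residue keys ("chain:resid:resname"),
#'   ordered by residue number
#' @export
significant_residues <- function(table_a, table_b, threshold = 0.10,
                                 mode = c("pooled", "any_replicate")) {
  mode <- match.arg(mode)
  if (threshold <= 0 || threshold > 1)
    stop("threshold must lie in (0, 1]")
  if (!identical(rownames(table_a$fractions), rownames(table_b$fractions)))
    stop("conditions must share a residue universe")
  hit <- function(tab) {
    if (mode == "pooled") pooled_fractions(tab) >= threshold
    else apply(tab$fractions >= threshold, 1, any)
  }
  keys <- rownames(table_a$fractions)
  sel <- keys[hit(table_a) | hit(table_b)]
  resid <- as.integer(vapply(strsplit(sel, ":"), `[`, "", 2))
  sel[order(resid)]
}

#' Contact heatmap table (residue x replicate percentages)
#'
#' @param tab a [contact_table()]
#' @param residues residue keys to include (default: all rows); rows are
#'   ordered by residue number
#' @return data.frame with `residue` plus one percentage column per
#'   replicate (100 x fraction)
#' @export
contact_heatmap_table <- function(tab, residues = rownames(tab$fractions)) {
  m <- tab$fractions[residues, , drop = FALSE] * 100
  resid <- as.integer(vapply(strsplit(residues, ":"), `[`, "", 2))
  ord <- order(resid)
  out <- data.frame(residue = residues[ord], m[ord, , drop = FALSE],
                    check.names = FALSE, stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}
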