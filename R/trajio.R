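# Structure / trajectory / volume file formats.
#
# Internal length unit is Angstrom throughout; times are ns. Readers do no
# periodic-boundary imaging: trajectories are expected to contain whole,
# unwrapped molecules, as produced by the simulation exporter.

# Two-letter element symbols that occur left-justified in PDB atom names.
TWO_LETTER_ELEMENTS <- c("FE", "ZN", "MG", "MN", "CA", "NA", "CL", "BR",
                         "CU", "NI", "CO", "SE", "CD", "HG", "LI", "AL", "SI")

infer_element <- function(name_field, element_field = "") {
  el <- trimws(element_field)
  if (nzchar(el)) return(paste0(toupper(substr(el, 1, 1)),
                                tolower(substring(el, 2))))
  # PDB rule: element begins in column 13 only for two-letter elements;
  # names like " CA " are carbon, "CA  " starting in column 13 is calcium.
  first <- substr(name_field, 1, 1)
  two <- toupper(substr(name_field, 1, 2))
  if (first != " " && two %in% TWO_LETTER_ELEMENTS)
    return(paste0(substr(two, 1, 1), tolower(substr(two, 2, 2))))
  nm <- trimws(name_field)
  nm <- sub("^[0-9']+", "", nm)          # e.g. "1HB" -> "HB"
  if (!nzchar(nm)) stop("cannot infer element from atom name '",
                        name_field, "'")
  toupper(substr(nm, 1, 1))
}

pdb_num <- function(s, lineno, what) {
  v <- suppressWarnings(as.numeric(s))
  if (is.na(v))
    stop(sprintf("PDB parse error at line %d: bad %s field '%s'",
                 lineno, what, s))
  v
}

#' Read a PDB structure
#'
#' Parses ATOM/HETATM records by fixed columns (PDB v3.3 subset) into a
#' [topology()] plus one frame of coordinates in Angstrom. Alternate
#' locations are resolved by keeping altloc "A" or blank and dropping the
#' rest (with a warning), so downstream analyses see one conformer per
#' atom. Elements are taken from columns 77-78 when present and inferred
#' from the atom-name field otherwise. Author residue numbering is kept
#' verbatim.
#'
#' @param path PDB file
#' @return list with elements `topology` and `coords` (n_atoms x 3 matrix)
#' @export
read_pdb <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path, warn = FALSE)
  rec <- substr(lines, 1, 6)
  sel <- which(rec == "ATOM  " | rec == "HETATM")
  if (length(sel) == 0) stop("no ATOM/HETATM records in ", path)

  n <- length(sel)
  serial <- integer(n); name <- character(n); alt <- character(n)
  resname <- character(n); chain <- character(n); resid <- integer(n)
  xyz <- matrix(0, n, 3); occ <- numeric(n); bf <- numeric(n)
  elem <- character(n)
  for (i in seq_len(n)) {
    ln <- lines[sel[i]]
    lno <- sel[i]
    if (nchar(ln) < 54)
      stop(sprintf("PDB parse error at line %d: record shorter than coordinate fields", lno))
    serial[i] <- as.integer(pdb_num(substr(ln, 7, 11), lno, "serial"))
    namef <- substr(ln, 13, 16)
    name[i] <- trimws(namef)
    alt[i] <- substr(ln, 17, 17)
    resname[i] <- trimws(substr(ln, 18, 21))
    chain[i] <- substr(ln, 22, 22)
    resid[i] <- as.integer(pdb_num(substr(ln, 23, 26), lno, "resSeq"))
    xyz[i, 1] <- pdb_num(substr(ln, 31, 38), lno, "x")
    xyz[i, 2] <- pdb_num(substr(ln, 39, 46), lno, "y")
    xyz[i, 3] <- pdb_num(substr(ln, 47, 54), lno, "z")
    occ[i] <- if (nchar(ln) >= 60 && nzchar(trimws(substr(ln, 55, 60))))
      pdb_num(substr(ln, 55, 60), lno, "occupancy") else 1
    bf[i] <- if (nchar(ln) >= 66 && nzchar(trimws(substr(ln, 61, 66))))
      pdb_num(substr(ln, 61, 66), lno, "bfactor") else 0
    elem[i] <- infer_element(namef, if (nchar(ln) >= 78)
      substr(ln, 77, 78) else "")
  }

  keep <- alt %in% c(" ", "", "A")
  if (!all(keep))
    warning(sum(!keep), " alternate-location atoms dropped (kept altloc 'A'/blank)")
  atoms <- data.frame(serial = serial, name = name, element = elem,
                      resname = resname, resid = resid, chain = chain,
                      occupancy = occ, bfactor = bf,
                      stringsAsFactors = FALSE)[keep, , drop = FALSE]
  list(topology = topology(atoms), coords = xyz[keep, , drop = FALSE])
}

pdb_name_field <- function(name, element) {
  # one-letter elements are indented to column 14, two-letter start at 13
  if (nchar(name) >= 4 || nchar(element) == 2) sprintf("%-4s", name)
  else sprintf(" %-3s", name)
}

#' Write a PDB structure
#'
#' Inverse of [read_pdb()]: metadata and coordinates round-trip to three
#' decimals. Coordinates with magnitude >= 1e4 Angstrom overflow the
#' fixed-width field and are refused.
#'
#' @param top topology
#' @param coords n_atoms x 3 matrix in Angstrom
#' @param path output file
#' @return `path`, invisibly
#' @export
write_pdb <- function(top, coords, path) {
  coords <- as.matrix(coords)
  if (nrow(coords) != n_atoms(top) || ncol(coords) != 3)
    stop("coords shape does not match topology")
  if (any(abs(coords) >= 1e4))
    stop("coordinate magnitude >= 10^4 Angstrom overflows the PDB field width")
  a <- top$atoms
  lines <- sprintf(
    "%-6s%5d %s %-4s%s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
    ifelse(a$resname %in% WATER_RESNAMES | !grepl("^[A-Z]{3}$", a$resname),
           "HETATM", "ATOM"),
    a$serial %% 100000L,
    vapply(seq_len(nrow(a)),
           function(i) pdb_name_field(a$name[i], a$element[i]), ""),
    a$resname, a$chain, a$resid %% 10000L,
    coords[, 1], coords[, 2], coords[, 3],
    a$occupancy, a$bfactor, toupper(a$element))
  writeLines(c(lines, "END"), path)
  invisible(path)
}

#' Read an XYZ trajectory
#'
#' Reads the plain XYZ dialect: per frame, a line with the atom count, a
#' comment line, then one "name x y z" line per atom. The atom count must
#' be constant across frames and match the supplied topology; XYZ carries
#' no residue metadata, so a topology (normally from the companion PDB)
#' is mandatory.
#'
#' @param path XYZ file
#' @param top topology describing the atoms (order must match)
#' @param frame_interval ns between frames
#' @param condition_label,replicate_id passed to [trajectory()]
#' @return a [trajectory()]
#' @export
read_xyz_traj <- function(path, top, frame_interval,
                          condition_label = "", replicate_id = "") {
  lines <- readLines(path, warn = FALSE)
  na <- n_atoms(top)
  pos <- 1L
  frames <- list()
  f <- 0L
  while (pos <= length(lines) && nzchar(trimws(lines[pos]))) {
    f <- f + 1L
    cnt <- suppressWarnings(as.integer(trimws(lines[pos])))
    if (is.na(cnt)) stop("frame ", f, ": bad atom-count line")
    if (cnt != na)
      stop("frame ", f, ": atom count ", cnt,
           " differs from topology (", na, ")")
    if (pos + 1L + cnt > length(lines))
      stop("truncated final frame ", f)
    block <- lines[(pos + 2L):(pos + 1L + cnt)]
    parts <- strsplit(trimws(block), "\\s+")
    bad <- which(lengths(parts) < 4)
    if (length(bad) > 0) stop("frame ", f, ": malformed atom line ", bad[1])
    m <- matrix(as.numeric(unlist(lapply(parts, `[`, 2:4))),
                ncol = 3, byrow = TRUE)
    if (any(is.na(m))) stop("frame ", f, ": non-numeric coordinate")
    frames[[f]] <- m
    pos <- pos + 2L + cnt
  }
  if (f == 0L) stop("no frames in ", path)
  coords <- array(0, c(f, na, 3))
  for (i in seq_len(f)) coords[i, , ] <- frames[[i]]
  trajectory(top, coords, frame_interval,
             condition_label = condition_label, replicate_id = replicate_id)
}

#' Write an XYZ trajectory
#'
#' @param traj trajectory
#' @param path output file
#' @return `path`, invisibly
#' @export
write_xyz_traj <- function(traj, path) {
  na <- n_atoms(traj$topology)
  nm <- traj$topology$atoms$name
  con <- file(path, "w")
  on.exit(close(con))
  for (f in seq_len(n_frames(traj))) {
    co <- frame_coords(traj, f)
    writeLines(c(as.character(na), sprintf("frame %d", f),
                 sprintf("%-4s %14.6f %14.6f %14.6f",
                         nm, co[, 1], co[, 2], co[, 3])), con)
  }
  invisible(path)
}

read_fortran_record <- function(con, endian, what = "raw") {
  len <- readBin(con, "integer", 1, size = 4, endian = endian)
  if (length(len) == 0 || len < 0) stop("DCD format error: bad record marker")
  payload <- readBin(con, "raw", len)
  if (length(payload) < len) stop("DCD format error: truncated record")
  tail <- readBin(con, "integer", 1, size = 4, endian = endian)
  if (length(tail) == 0 || tail != len)
    stop("DCD format error: record trailer mismatch")
  payload
}

#' Read a CHARMM/NAMD DCD trajectory
#'
#' Binary read-only reader. Both byte orders are accepted (detected from
#' the leading record marker). Fixed-atom DCDs are rejected. The frame
#' count in the header must be consistent with the file size.
#'
#' @param path DCD file
#' @param top topology (atom count must match the DCD)
#' @param frame_interval ns between frames (DCD time metadata is ignored;
#'   the saving interval is not recoverable portably)
#' @param condition_label,replicate_id passed to [trajectory()]
#' @return a [trajectory()]
#' @export
read_dcd <- function(path, top, frame_interval,
                     condition_label = "", replicate_id = "") {
  fsize <- file.info(path)$size
  if (is.na(fsize) || fsize < 4) stop("DCD format error: file too small")
  con <- file(path, "rb")
  on.exit(close(con))
  first <- readBin(con, "raw", 4)
  endian <- NULL
  for (e in c("little", "big")) {
    if (readBin(first, "integer", 1, size = 4, endian = e) == 84L) {
      endian <- e
      break
    }
  }
  if (is.null(endian))
    stop("DCD format error: leading header record is not 84 bytes")
  seek(con, 0)

  hdr <- read_fortran_record(con, endian)
  if (length(hdr) != 84 || rawToChar(hdr[1:4]) != "CORD")
    stop("DCD format error: missing CORD magic")
  icntrl <- readBin(hdr[5:84], "integer", 20, size = 4, endian = endian)
  nset <- icntrl[1]
  namnf <- icntrl[9]
  cell_flag <- icntrl[11] != 0
  if (namnf != 0)
    stop("fixed-atom DCD files are not supported")

  title <- read_fortran_record(con, endian)  # ignored
  natom_rec <- read_fortran_record(con, endian)
  natom <- readBin(natom_rec, "integer", 1, size = 4, endian = endian)
  if (natom != n_atoms(top))
    stop("DCD atom count (", natom, ") does not match topology (",
         n_atoms(top), ")")

  header_bytes <- seek(con)
  frame_bytes <- (if (cell_flag) 48 + 8 else 0) + 3 * (4 * natom + 8)
  remaining <- fsize - header_bytes
  if (remaining %% frame_bytes != 0 || remaining / frame_bytes != nset)
    stop("DCD format error: header frame count (", nset,
         ") inconsistent with file size (holds ",
         remaining / frame_bytes, " frames)")

  coords <- array(0, c(nset, natom, 3))
  for (f in seq_len(nset)) {
    if (cell_flag) read_fortran_record(con, endian)
    for (d in 1:3) {
      rec <- read_fortran_record(con, endian)
      coords[f, , d] <- readBin(rec, "numeric", natom, size = 4,
                                endian = endian)
    }
  }
  trajectory(top, coords, frame_interval,
             condition_label = condition_label, replicate_id = replicate_id)
}

#' Write an occupancy grid as an OpenDX map
#'
#' Emits the ASCII "gridpositions/gridconnections" OpenDX layout used to
#' overlay volumetric maps on atomic structures in molecular viewers.
#' Origin and voxel deltas are in Angstrom; data values run z-fastest
#' (the standard DX convention).
#'
#' @param grid an [occupancy_grid_obj()]
#' @param path output file
#' @return `path`, invisibly
#' @export
write_dx <- function(grid, path) {
  v <- grid$values
  if (!all(is.finite(v))) stop("grid values must be finite")
  sh <- grid$shape
  d <- grid$voxel_edge
  # z-fastest flattening of values[i, j, k]: after aperm to (k, j, i),
  # column-major as.vector runs k fastest, i slowest
  flat <- as.vector(aperm(v, c(3, 2, 1)))
  lines <- c(
    sprintf("object 1 class gridpositions counts %d %d %d", sh[1], sh[2], sh[3]),
    sprintf("origin %.6f %.6f %.6f", grid$origin[1], grid$origin[2], grid$origin[3]),
    sprintf("delta %.6f 0.000000 0.000000", d),
    sprintf("delta 0.000000 %.6f 0.000000", d),
    sprintf("delta 0.000000 0.000000 %.6f", d),
    sprintf("object 2 class gridconnections counts %d %d %d", sh[1], sh[2], sh[3]),
    sprintf("object 3 class array type double rank 0 items %d data follows",
            prod(sh)))
  # three values per line
  grp <- split(flat, (seq_along(flat) - 1) %/% 3)
  body <- vapply(grp, function(g) paste(sprintf("%.6g", g), collapse = " "), "")
  lines <- c(lines, body,
             'attribute "dep" string "positions"',
             'object "occupancy" class field',
             'component "positions" value 1',
             'component "connections" value 2',
             'component "data" value 3')
  writeLines(lines, path)
  invisible(path)
}

#' Write a tab-separated table
#'
#' Locale-independent TSV: tab separators, "." decimal point, one header
#' line, numeric values at 6 significant digits.
#'
#' @param rows data.frame, or list of equal-length row vectors
#' @param header character vector of column names
#' @param path output file
#' @return `path`, invisibly
#' @export
write_table <- function(rows, header, path) {
  if (is.data.frame(rows)) rows <- lapply(seq_len(nrow(rows)),
                                          function(i) as.list(rows[i, ]))
  nc <- length(header)
  fmt_cell <- function(x) {
    if (is.numeric(x) && !is.integer(x)) sprintf("%.6g", x)
    else as.character(x)
  }
  lines <- paste(header, collapse = "\t")
  for (r in rows) {
    if (length(r) != nc)
      stop("ragged row: ", length(r), " fields, header has ", nc)
    lines <- c(lines, paste(vapply(r, fmt_cell, ""), collapse = "\t"))
  }
  writeLines(lines, path)
  invisible(path)
}
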