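# Superposition and RMSD.
#
# All trajectory superpositions fit on a user-chosen selection (backbone
# heavy atoms by default) against a designated post-equilibration
# reference frame; measurement selections are independent of the fit
# selection, so e.g. a ligand RMSD is measured in the frame defined by a
# backbone fit.

sel_indices <- function(sel) {
  if (inherits(sel, "selection")) sel$indices else as.integer(sel)
}

#' Kabsch superposition of one frame onto a reference
#'
#' Finds the proper rotation and translation minimizing the RMSD between
#' the selected atoms of `mobile` and `reference`, by SVD of the
#' cross-covariance of the mean-centered point sets with the usual
#' determinant-sign correction that excludes reflections.
#'
#' The returned transform maps mobile coordinates x to
#' `x %*% t(rotation) + translation` (row vectors).
#'
#' @param mobile n_atoms x 3 coordinate matrix (Angstrom)
#' @param reference n_atoms x 3 coordinate matrix on the same atom order
#' @param sel a [selection()] (or integer indices) of >= 3 non-collinear
#'   atoms used for the fit
#' @return list of class `superposition` with `rotation` (3x3, proper
#'   orthogonal), `translation` (length 3) and `rmsd` (Angstrom, over the
#'   fit selection)
#' @export
kabsch_superpose <- function(mobile, reference, sel) {
  idx <- sel_indices(sel)
  if (length(idx) < 3)
    stop("degenerate geometry: superposition needs >= 3 selected atoms")
  A <- as.matrix(mobile)[idx, , drop = FALSE]
  B <- as.matrix(reference)[idx, , drop = FALSE]
  ca <- colMeans(A)
  cb <- colMeans(B)
  A0 <- sweep(A, 2, ca)
  B0 <- sweep(B, 2, cb)
  H <- crossprod(A0, B0)                 # 3x3 covariance
  sv <- svd(H)
  if (sv$d[2] < 1e-10 * max(sv$d[1], 1e-300))
    stop("degenerate geometry: selected atoms are (nearly) collinear")
  d <- sign(det(sv$v %*% t(sv$u)))
  if (d == 0) stop("degenerate geometry: singular covariance")
  D <- diag(c(1, 1, d))
  R <- sv$v %*% D %*% t(sv$u)            # maps centered mobile onto centered ref
  fitted <- A0 %*% t(R)
  rmsd <- sqrt(mean(rowSums((fitted - B0)^2)))
  structure(list(rotation = R,
                 translation = as.numeric(cb - ca %*% t(R)),
                 rmsd = rmsd),
            class = "superposition")
}

#' @export
print.superposition <- function(x, ...) {
  cat(sprintf("superposition: rmsd = %.4f A\n", x$rmsd))
  invisible(x)
}

apply_superposition <- function(coords, sp) {
  sweep(as.matrix(coords) %*% t(sp$rotation), 2, sp$translation, `+`)
}

#' Align every trajectory frame to a reference
#'
#' Each frame gets its own Kabsch fit on `fit_sel` against the reference
#' frame; the resulting rigid transform is applied to all atoms of that
#' frame. Re-aligning an already aligned trajectory changes coordinates
#' by less than numerical noise.
#'
#' @param traj a [trajectory()]
#' @param reference n_atoms x 3 reference coordinates (the designated
#'   post-equilibration reference frame)
#' @param fit_sel selection fitted on; defaults to the backbone atoms
#' @return the aligned trajectory, with its `aligned` flag set
#' @export
align_trajectory <- function(traj, reference,
                             fit_sel = select_atoms(traj$topology, "backbone")) {
  out <- traj$coords
  for (f in seq_len(n_frames(traj))) {
    sp <- kabsch_superpose(frame_coords(traj, f), reference, fit_sel)
    out[f, , ] <- apply_superposition(frame_coords(traj, f), sp)
  }
  trajectory(traj$topology, out, traj$frame_interval,
             condition_label = traj$condition_label,
             replicate_id = traj$replicate_id, aligned = TRUE)
}

#' RMSD time series against a reference
#'
#' Per frame, the root-mean-square displacement of the measured selection
#' from the reference, in Angstrom. No re-fitting happens here: the
#' trajectory must already be aligned (see [align_trajectory()]), so the
#' measure selection can differ from the fit selection.
#'
#' @param traj aligned [trajectory()]
#' @param reference n_atoms x 3 reference coordinates
#' @param measure_sel selection the deviation is measured over
#' @return numeric vector, one RMSD per frame
#' @export
rmsd_series <- function(traj, reference, measure_sel) {
  idx <- sel_indices(measure_sel)
  if (length(idx) == 0) stop("empty measure selection")
  ref <- as.matrix(reference)[idx, , drop = FALSE]
  vapply(seq_len(n_frames(traj)), function(f) {
    d <- frame_coords(traj, f)[idx, , drop = FALSE] - ref
    sqrt(mean(rowSums(d^2)))
  }, 0)
}

#' Bundle per-replicate series on a common time grid
#'
#' @param time numeric vector of times (ns), strictly increasing
#' @param values list of numeric vectors, one per replicate; replicates
#'   of unequal length are truncated to the shortest on aggregation
#' @param condition_label condition the replicates belong to
#' @return object of class `series_bundle`
#' @export
series_bundle <- function(time, values, condition_label = "") {
  if (length(values) == 0) stop("empty series bundle")
  if (is.unsorted(time, strictly = TRUE)) stop("time must be strictly increasing")
  if (max(lengths(values)) > length(time))
    stop("a replicate is longer than the time grid")
  structure(list(time = time, values = values,
                 condition_label = condition_label),
            class = "series_bundle")
}

#' Aggregate replicate series into mean and SEM
#'
#' Replicates are truncated to the shortest series, then the mean and the
#' standard error of the mean (sample sd / sqrt(n), n-1 denominator) are
#' computed at every time point. With a single replicate the SEM is
#' reported as NA.
#'
#' @param bundle a [series_bundle()]
#' @return list of class `aggregated_series` with `time`, `mean`, `sem`,
#'   `n_replicates`
#' @export
aggregate_replicates <- function(bundle) {
  vals <- bundle$values
  nrep <- length(vals)
  len <- min(lengths(vals))
  if (len == 0) stop("a replicate has no data")
  m <- do.call(cbind, lapply(vals, function(v) v[seq_len(len)]))
  mu <- rowMeans(m)
  sem <- if (nrep >= 2) apply(m, 1, stats::sd) / sqrt(nrep)
         else rep(NA_real_, len)
  structure(list(time = bundle$time[seq_len(len)], mean = mu, sem = sem,
                 n_replicates = nrep,
                 condition_label = bundle$condition_label),
            class = "aggregated_series")
}

#' @export
print.aggregated_series <- function(x, ...) {
  cat(sprintf("aggregated series: %d time points, n = %d replicates\n",
              length(x$time), x$n_replicates))
  invisible(x)
}
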