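# Solvent-shell counts and voxelized water-occupancy maps.
#
# A water molecule is counted once, by its oxygen position ("oxygen"
# mode, the default); "any_atom" mode counts every water atom and is
# provided for sensitivity checks. Shell membership uses a strict "<"
# at the radius. Voxel membership is half-open,
# [origin + i*edge, origin + (i+1)*edge), so a point on a voxel face
# belongs to exactly one voxel.

water_atom_indices <- function(top, water_mode = c("oxygen", "any_atom")) {
  water_mode <- match.arg(water_mode)
  w <- which(mask_water(top))
  if (length(w) == 0) stop("no water atoms in topology")
  if (water_mode == "oxygen") w <- w[top$atoms$element[w] == "O"]
  if (length(w) == 0) stop("no water oxygen atoms in topology")
  w
}

#' Shell specification around a single atom
#'
#' @param center_sel single-atom selection (e.g. the C-alpha of the Na2
#'   lysine, or the ligand C-alpha)
#' @param radius shell radius; accepts "10A"/"1nm" (default 10 Angstrom)
#' @return object of class `shell_spec`
#' @export
shell_spec <- function(center_sel, radius = 10) {
  radius <- parse_length(radius)
  if (radius <= 0) stop("shell radius must be positive")
  idx <- sel_indices(center_sel)
  if (length(idx) != 1)
    stop("shell center selection must contain exactly one atom, got ",
         length(idx))
  structure(list(center = idx, radius = radius), class = "shell_spec")
}

#' Water count inside a moving shell, per frame
#'
#' For every frame, the number of water molecules whose counted atom lies
#' strictly within `radius` of the center atom's current position.
#'
#' @param traj aligned [trajectory()]
#' @param shell a [shell_spec()]
#' @param water_mode "oxygen" (one count per molecule) or "any_atom"
#' @return integer vector of counts per frame
#' @export
water_count_series <- function(traj, shell,
                               water_mode = c("oxygen", "any_atom")) {
  w <- water_atom_indices(traj$topology, water_mode)
  r2 <- shell$radius^2
  nf <- n_frames(traj)
  out <- integer(nf)
  for (f in seq_len(nf)) {
    ctr <- traj$coords[f, shell$center, ]
    d2 <- (traj$coords[f, w, 1] - ctr[1])^2 +
          (traj$coords[f, w, 2] - ctr[2])^2 +
          (traj$coords[f, w, 3] - ctr[3])^2
    out[f] <- sum(d2 < r2)
  }
  out
}

#' Restrict a time series to its steady-state window
#'
#' Keeps frames with t > start_time. The default start of 400 ns is where
#' water permeation through the transporter core plateaus in the study
#' system; it is a parameter, not a detected quantity.
#'
#' @param series numeric vector (one value per frame)
#' @param time numeric vector of frame times (ns)
#' @param start_time window start in ns (default 400)
#' @return list with `series`, `time` (both truncated) and `n_frames`
#' @export
steady_state_window <- function(series, time, start_time = 400) {
  if (length(series) != length(time)) stop("series/time length mismatch")
  if (start_time > max(time))
    stop("window start ", start_time, " ns is beyond the series span")
  # strict ">" after the start; a start of 0 (or less) keeps every frame
  keep <- if (start_time > 0) time > start_time else rep(TRUE, length(time))
  if (!any(keep)) stop("steady-state window is empty")
  list(series = series[keep], time = time[keep], n_frames = sum(keep))
}

#' Report a plateau start by a sliding-window criterion
#'
#' Advisory detector for the steady-state start: the earliest time from
#' which every subsequent sliding-window mean stays within one SEM of the
#' mean over the final 20% of the series. It only reports; it never
#' overrides the user-supplied window start.
#'
#' @param series numeric vector
#' @param time frame times (ns)
#' @param window_frames sliding-window width in frames
#' @return detected start time (ns), or NA when no plateau is found
#' @export
detect_plateau_start <- function(series, time,
                                 window_frames = max(5L, length(series) %/% 20L)) {
  n <- length(series)
  tail_idx <- seq.int(floor(0.8 * n) + 1, n)
  ref_mean <- mean(series[tail_idx])
  ref_sem <- stats::sd(series[tail_idx]) / sqrt(length(tail_idx))
  if (!is.finite(ref_sem) || ref_sem == 0) ref_sem <- stats::sd(series) / sqrt(n)
  wmean <- stats::filter(series, rep(1 / window_frames, window_frames),
                         sides = 1)
  ok <- abs(wmean - ref_mean) <= ref_sem
  ok[is.na(ok)] <- FALSE
  # earliest index from which all later windows stay inside the band
  good_from <- rev(cumprod(rev(ok))) == 1
  if (!any(good_from)) return(NA_real_)
  time[which(good_from)[1]]
}

#' Construct an occupancy grid object
#'
#' @param origin length-3 grid origin (Angstrom)
#' @param voxel_edge voxel edge length (Angstrom)
#' @param values 3D array of occupancy fractions in [0, 1]
#' @param frames_used number of frames the fractions average over
#' @param region_label descriptive label
#' @return object of class `occupancy_grid`
#' @export
occupancy_grid_obj <- function(origin, voxel_edge, values, frames_used,
                               region_label = "") {
  if (any(values < 0 | values > 1)) stop("occupancies must lie in [0, 1]")
  if (frames_used < 1) stop("frames_used must be >= 1")
  structure(list(origin = as.numeric(origin),
                 voxel_edge = as.numeric(voxel_edge),
                 shape = dim(values), values = values,
                 frames_used = as.integer(frames_used),
                 region_label = region_label),
            class = "occupancy_grid")
}

#' @export
print.occupancy_grid <- function(x, ...) {
  cat(sprintf("occupancy grid %dx%dx%d, edge %.2f A, %d frames%s\n",
              x$shape[1], x$shape[2], x$shape[3], x$voxel_edge,
              x$frames_used,
              if (nzchar(x$region_label)) paste0(" (", x$region_label, ")")
              else ""))
  invisible(x)
}

voxel_index <- function(points, origin, edge, shape) {
  # half-open voxels; returns NA rows for points outside the region
  ijk <- floor(sweep(points, 2, origin) / edge) + 1
  out <- matrix(as.integer(ijk), ncol = 3)
  bad <- out[, 1] < 1 | out[, 1] > shape[1] |
         out[, 2] < 1 | out[, 2] > shape[2] |
         out[, 3] < 1 | out[, 3] > shape[3]
  out[bad, ] <- NA_integer_
  out
}

#' Voxelized water-occupancy map
#'
#' For each voxel of a rectangular region, the fraction of (windowed,
#' pooled) frames in which at least one counted water atom lies inside
#' the voxel. Multiple trajectories (e.g. all replicates of a condition)
#' are pooled frame-wise; at display time an isosurface threshold of 0.1
#' corresponds to water present in 10% of snapshots.
#'
#' @param trajs a [trajectory()] or list of trajectories sharing one
#'   topology (pooled)
#' @param region list with `min` and `max` length-3 corners (Angstrom)
#' @param voxel_edge voxel edge length in Angstrom (default 1.0)
#' @param water_mode "oxygen" or "any_atom"
#' @param start_time only frames with t > start_time enter (ns, default 0)
#' @param region_label label stored on the grid
#' @return an [occupancy_grid_obj()]
#' @export
occupancy_grid <- function(trajs, region, voxel_edge = 1.0,
                           water_mode = c("oxygen", "any_atom"),
                           start_time = 0, region_label = "") {
  if (inherits(trajs, "trajectory")) trajs <- list(trajs)
  voxel_edge <- parse_length(voxel_edge)
  if (voxel_edge <= 0) stop("voxel_edge must be positive")
  lo <- as.numeric(region$min)
  hi <- as.numeric(region$max)
  if (any(hi <= lo)) stop("degenerate grid region")
  shape <- as.integer(ceiling((hi - lo) / voxel_edge - 1e-9))
  present <- array(0L, shape)
  frames_used <- 0L
  for (traj in trajs) {
    w <- water_atom_indices(traj$topology, water_mode)
    times <- frame_times(traj)
    fsel <- if (start_time > 0) which(times > start_time)
            else seq_along(times)
    for (f in fsel) {
      pts <- matrix(traj$coords[f, w, ], ncol = 3)
      ijk <- voxel_index(pts, lo, voxel_edge, shape)
      ijk <- unique(ijk[!is.na(ijk[, 1]), , drop = FALSE])
      if (nrow(ijk) > 0) present[ijk] <- present[ijk] + 1L
      frames_used <- frames_used + 1L
    }
  }
  if (frames_used == 0L) stop("occupancy window contains no frames")
  occupancy_grid_obj(lo, voxel_edge, present / frames_used, frames_used,
                     region_label)
}

#' Mask an occupancy grid to voxels near reference points
#'
#' Zeroes voxels whose centers lie farther than `radius` from every
#' reference point; used to restrict occupancy reporting to e.g. within
#' 10 Angstrom of the substrate or a binding-site residue.
#'
#' @param grid an [occupancy_grid_obj()]
#' @param points k x 3 matrix of reference coordinates
#' @param radius distance in Angstrom (accepts unit suffixes)
#' @return the masked grid
#' @export
mask_grid_near <- function(grid, points, radius = 10) {
  radius <- parse_length(radius)
  points <- matrix(points, ncol = 3)
  sh <- grid$shape
  centers_1d <- lapply(1:3, function(d)
    grid$origin[d] + (seq_len(sh[d]) - 0.5) * grid$voxel_edge)
  ctr <- as.matrix(expand.grid(centers_1d[[1]], centers_1d[[2]],
                               centers_1d[[3]]))
  d2 <- matrix(Inf, nrow(ctr), 1)
  for (k in seq_len(nrow(points)))
    d2 <- pmin(d2, rowSums(sweep(ctr, 2, points[k, ])^2))
  keep <- array(d2 <= radius^2, sh)
  v <- grid$values
  v[!keep] <- 0
  occupancy_grid_obj(grid$origin, grid$voxel_edge, v, grid$frames_used,
                     grid$region_label)
}

#' Compare experimentally modeled waters with an occupancy map
#'
#' For each experimental water position, reports the occupancy of its
#' containing voxel and a call: "supported" when that occupancy reaches
#' the threshold, "unsupported" otherwise, "out_of_region" when the water
#' lies outside the grid (flagged, not scored). The summary fraction is
#' over in-region waters.
#'
#' @param grid an [occupancy_grid_obj()]
#' @param water_coords k x 3 matrix of experimental water positions
#'   (Angstrom), e.g. HOH oxygens from [read_pdb()]
#' @param threshold occupancy threshold (default 0.1, i.e. present in 10%
#'   of snapshots)
#' @return list with `report` (data.frame: water, occupancy, call) and
#'   `fraction_supported`
#' @export
colocalize_waters <- function(grid, water_coords, threshold = 0.1) {
  pts <- matrix(water_coords, ncol = 3)
  ijk <- voxel_index(pts, grid$origin, grid$voxel_edge, grid$shape)
  occ <- rep(NA_real_, nrow(pts))
  inreg <- !is.na(ijk[, 1])
  if (any(inreg)) occ[inreg] <- grid$values[ijk[inreg, , drop = FALSE]]
  call <- ifelse(!inreg, "out_of_region",
                 ifelse(occ >= threshold, "supported", "unsupported"))
  report <- data.frame(water = seq_len(nrow(pts)), occupancy = occ,
                       call = call, stringsAsFactors = FALSE)
  frac <- if (any(inreg)) mean(occ[inreg] >= threshold) else NA_real_
  list(report = report, fraction_supported = frac)
}
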