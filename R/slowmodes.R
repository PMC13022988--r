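# Time-lagged independent component analysis and free-energy surfaces.
#
# tICA linearly transforms structural descriptors into orthogonal
# coordinates that maximize autocorrelation at a chosen lag time,
# approximating the slow eigenmodes of the underlying propagator. A
# single model is trained on the combined conditions so the component
# definitions are shared across systems; free-energy surfaces are then
# histogrammed per condition on common axes.

#' Build a feature matrix from an aligned trajectory
#'
#' Row t is the flattened (x1, y1, z1, x2, ...) coordinates of the
#' selected atoms at frame t, so d = 3 x n_selected. Features must come
#' from superposed frames — an unaligned trajectory is refused, since
#' global rotation/translation would otherwise dominate the slow modes.
#'
#' @param traj aligned [trajectory()]
#' @param sel atom selection (e.g. ligand heavy atoms, or the helix-break
#'   region heavy atoms)
#' @param feature_label descriptive label ("ligand_coords",
#'   "break_region_heavy", ...)
#' @return object of class `feature_matrix`
#' @export
extract_features <- function(traj, sel, feature_label = "") {
  if (!isTRUE(traj$aligned))
    stop("features require an aligned trajectory; run align_trajectory() first")
  idx <- sel_indices(sel)
  if (length(idx) == 0) stop("empty feature selection")
  nf <- n_frames(traj)
  X <- matrix(0, nf, 3 * length(idx))
  for (f in seq_len(nf))
    X[f, ] <- as.vector(t(matrix(traj$coords[f, idx, ], ncol = 3)))
  feature_matrix(X, feature_label = feature_label,
                 condition_label = traj$condition_label,
                 replicate_id = traj$replicate_id,
                 frame_interval = traj$frame_interval)
}

#' Construct a feature matrix directly
#'
#' @param X frames x d numeric matrix
#' @param feature_label,condition_label,replicate_id metadata strings
#' @param frame_interval ns per frame
#' @return object of class `feature_matrix`
#' @export
feature_matrix <- function(X, feature_label = "", condition_label = "",
                           replicate_id = "", frame_interval = 1) {
  X <- as.matrix(X)
  if (!all(is.finite(X))) stop("features must be finite")
  structure(list(X = X, feature_label = feature_label,
                 condition_label = condition_label,
                 replicate_id = replicate_id,
                 frame_interval = frame_interval),
            class = "feature_matrix")
}

#' Fit a tICA model on pooled trajectories
#'
#' Instantaneous (C0) and time-lagged (Ctau) covariances are accumulated
#' per trajectory so no lagged pair crosses a trajectory boundary; all
#' trajectories are centered on the single pooled mean. The lagged
#' covariance is symmetrized (reversible estimator), C0 is regularized by
#' adding `epsilon` times the identity, and the generalized symmetric
#' eigenproblem Ctau_sym v = lambda C0 v is solved by whitening.
#' Eigenpairs come back sorted by descending eigenvalue with a
#' deterministic sign convention (largest-magnitude loading positive);
#' components are C0-orthonormal.
#'
#' Training on the combined conditions (both protonation states) keeps
#' the component definitions consistent across systems; a warning is
#' raised when labeled features cover fewer than two conditions.
#'
#' @param features list of [feature_matrix()] objects (or a single one)
#' @param lag_frames lag time in frames (positive integer)
#' @param epsilon ridge added to C0; default 1e-6 * trace(C0)/d
#' @return object of class `tica_model`
#' @export
tica_fit <- function(features, lag_frames, epsilon = NULL) {
  if (inherits(features, "feature_matrix")) features <- list(features)
  lag_frames <- as.integer(lag_frames)
  if (lag_frames < 1) stop("lag_frames must be a positive integer")
  d <- ncol(features[[1]]$X)
  dt <- features[[1]]$frame_interval
  labels <- unique(vapply(features, function(f) f$condition_label, ""))
  if (any(nzchar(labels)) && length(labels[nzchar(labels)]) < 2)
    warning("features cover a single condition; components are not ",
            "guaranteed to transfer across conditions")
  for (f in features) {
    if (ncol(f$X) != d) stop("feature dimension mismatch across trajectories")
    if (nrow(f$X) <= lag_frames)
      stop("trajectory '", f$replicate_id, "' has ", nrow(f$X),
           " frames, not more than the lag (", lag_frames, ")")
  }

  # pooled mean over all frames entering pairs (head and tail windows)
  s <- numeric(d); nobs <- 0
  for (f in features) {
    T <- nrow(f$X)
    h <- seq_len(T - lag_frames); t2 <- h + lag_frames
    s <- s + colSums(f$X[h, , drop = FALSE]) + colSums(f$X[t2, , drop = FALSE])
    nobs <- nobs + 2 * (T - lag_frames)
  }
  mu <- s / nobs

  C0 <- matrix(0, d, d); Ct <- matrix(0, d, d); npairs <- 0
  for (f in features) {
    T <- nrow(f$X)
    h <- seq_len(T - lag_frames); t2 <- h + lag_frames
    Xh <- sweep(f$X[h, , drop = FALSE], 2, mu)
    Xt <- sweep(f$X[t2, , drop = FALSE], 2, mu)
    C0 <- C0 + crossprod(Xh) + crossprod(Xt)
    Ct <- Ct + crossprod(Xh, Xt)
    npairs <- npairs + (T - lag_frames)
  }
  C0 <- C0 / nobs
  Ct <- Ct / npairs
  Ct_sym <- (Ct + t(Ct)) / 2

  if (is.null(epsilon)) epsilon <- 1e-6 * sum(diag(C0)) / d
  C0r <- C0 + diag(epsilon, d)
  e0 <- eigen(C0r, symmetric = TRUE)
  if (min(e0$values) <= .Machine$double.eps * max(e0$values))
    stop("C0 is rank-deficient beyond the regularization; ",
         "increase epsilon")
  W <- e0$vectors %*% diag(1 / sqrt(e0$values), d) %*% t(e0$vectors)
  M <- W %*% Ct_sym %*% W
  M <- (M + t(M)) / 2
  em <- eigen(M, symmetric = TRUE)       # descending eigenvalues
  V <- W %*% em$vectors
  for (j in seq_len(d)) {
    i <- which.max(abs(V[, j]))
    if (V[i, j] < 0) V[, j] <- -V[, j]
  }
  structure(list(lag_frames = lag_frames, frame_interval = dt,
                 mean = mu, C0 = C0r, Ctau_sym = Ct_sym,
                 eigenvalues = em$values, components = V,
                 epsilon = epsilon, d = d),
            class = "tica_model")
}

#' @export
print.tica_model <- function(x, ...) {
  cat(sprintf("tICA model: d = %d, lag = %d frames (%.4g ns)\n",
              x$d, x$lag_frames, x$lag_frames * x$frame_interval))
  cat("  leading eigenvalues:",
      paste(sprintf("%.4f", utils::head(x$eigenvalues, 4)), collapse = " "),
      "\n")
  invisible(x)
}

#' Project features onto the leading tICA components
#'
#' y_t = V' (x_t - mean), keeping the first `k` components (default 2,
#' i.e. tIC-1 and tIC-2).
#'
#' @param model a [tica_model()]
#' @param features a [feature_matrix()] or plain frames x d matrix
#' @param k number of components to keep
#' @return frames x k matrix of projections
#' @export
tica_transform <- function(model, features, k = 2) {
  X <- if (inherits(features, "feature_matrix")) features$X else as.matrix(features)
  if (ncol(X) != model$d)
    stop("feature dimension (", ncol(X), ") does not match model (", model$d, ")")
  k <- min(k, model$d)
  sweep(X, 2, model$mean) %*% model$components[, seq_len(k), drop = FALSE]
}

#' Implied timescales of a tICA model
#'
#' t_i = -(lag_frames * frame_interval) / ln(lambda_i), in ns.
#' Eigenvalues outside (0, 1) have no finite relaxation time and are
#' reported as NA with a reason code instead of raising.
#'
#' @param model a [tica_model()]
#' @return data.frame with `component`, `eigenvalue`, `timescale_ns`,
#'   `status` ("ok", "nonpositive", "unit_or_larger")
#' @export
implied_timescales <- function(model) {
  lam <- model$eigenvalues
  tau <- model$lag_frames * model$frame_interval
  status <- ifelse(lam <= 0, "nonpositive",
                   ifelse(lam >= 1, "unit_or_larger", "ok"))
  ts <- ifelse(status == "ok", -tau / log(pmin(pmax(lam, 1e-300), 1 - 1e-16)),
               NA_real_)
  ts[status != "ok"] <- NA_real_
  data.frame(component = seq_along(lam), eigenvalue = lam,
             timescale_ns = ts, status = status,
             stringsAsFactors = FALSE)
}

#' Scan tICA lags (and dimensionalities)
#'
#' Fits one model per lag; the dimensionality only controls how many
#' components are reported, so a stable landscape across this table is
#' evidence the captured slow modes are robust to the model parameters.
#'
#' @param features list of [feature_matrix()]
#' @param lags integer vector of lags in frames
#' @param dims number of components to report (default up to 5)
#' @return data.frame, one row per lag, with eigenvalues `lambda_k` and
#'   implied timescales `t_k_ns` for k = 1..dims
#' @export
lag_scan <- function(features, lags, dims = 2) {
  dims <- max(dims)
  rows <- lapply(lags, function(lg) {
    m <- tica_fit(features, lg)
    it <- implied_timescales(m)
    k <- min(dims, m$d)
    row <- c(lag_frames = lg,
             lag_ns = lg * m$frame_interval,
             stats::setNames(m$eigenvalues[seq_len(k)],
                             paste0("lambda_", seq_len(k))),
             stats::setNames(it$timescale_ns[seq_len(k)],
                             paste0("t_", seq_len(k), "_ns")))
    as.data.frame(as.list(row))
  })
  do.call(rbind, rows)
}

#' Persist / restore a tICA model as JSON text
#'
#' Matrices are stored row-major at full decimal precision, so a
#' restored model reproduces projections to near machine precision.
#'
#' @param model a [tica_model()]
#' @param path output file
#' @return `path` (write) or the restored model (read)
#' @export
write_tica_model <- function(model, path) {
  obj <- list(schema = "transportdyn/tica_model/1",
              lag_frames = model$lag_frames,
              frame_interval = model$frame_interval,
              epsilon = model$epsilon, d = model$d,
              mean = model$mean,
              C0_rowmajor = as.vector(t(model$C0)),
              Ctau_sym_rowmajor = as.vector(t(model$Ctau_sym)),
              eigenvalues = model$eigenvalues,
              components_rowmajor = as.vector(t(model$components)))
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_tica_model
#' @export
read_tica_model <- function(path) {
  o <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(o$schema, "transportdyn/tica_model/1"))
    stop("not a tICA model file: ", path)
  d <- o$d
  structure(list(lag_frames = as.integer(o$lag_frames),
                 frame_interval = o$frame_interval,
                 mean = o$mean,
                 C0 = matrix(o$C0_rowmajor, d, d, byrow = TRUE),
                 Ctau_sym = matrix(o$Ctau_sym_rowmajor, d, d, byrow = TRUE),
                 eigenvalues = o$eigenvalues,
                 components = matrix(o$components_rowmajor, d, d, byrow = TRUE),
                 epsilon = o$epsilon, d = d),
            class = "tica_model")
}

#' Shared histogram edges across conditions
#'
#' Bin edges spanning the combined range of several projection sets, so
#' per-condition surfaces share axes.
#'
#' @param proj_list list of n x 2 projection matrices
#' @param bins number of bins per axis (default 60)
#' @return list with `x` and `y` edge vectors (length bins + 1)
#' @export
fes_bin_edges <- function(proj_list, bins = 60) {
  all <- do.call(rbind, lapply(proj_list, function(p) p[, 1:2, drop = FALSE]))
  pad <- 1e-9
  list(x = seq(min(all[, 1]) - pad, max(all[, 1]) + pad, length.out = bins + 1),
       y = seq(min(all[, 2]) - pad, max(all[, 2]) + pad, length.out = bins + 1))
}

#' Free-energy surface over two tICA components
#'
#' F = -kT ln(n_bin / n_max) on a 2D histogram of the projections, so
#' the most populated bin sits at F = 0 and every populated bin has
#' F >= 0. Empty bins are masked (NA), never zero. When comparing
#' conditions, compute `edges` once with [fes_bin_edges()] on the
#' combined data and pass them to each call.
#'
#' `min_count` masks bins with fewer samples than requested (treated as
#' empty): with strongly autocorrelated trajectories, bins visited only
#' a frame or two carry no reliable free-energy estimate and would
#' otherwise litter the surface with spurious shallow minima. The
#' default of 1 keeps every populated bin.
#'
#' @param proj n x 2 matrix of (tIC-1, tIC-2) projections
#' @param bins bins per axis, used when `edges` is NULL
#' @param kT thermal energy unit (default 1, i.e. F in kT)
#' @param edges optional list(x, y) of shared bin edges
#' @param min_count smallest bin count considered populated
#' @return object of class `fe_surface` with `F` (bins x bins, NA =
#'   empty or below `min_count`), `counts`, `xedges`, `yedges`, `kT`
#' @export
free_energy_surface <- function(proj, bins = 60, kT = 1, edges = NULL,
                                min_count = 1) {
  proj <- as.matrix(proj)
  if (nrow(proj) == 0) stop("no projection data")
  if (is.null(edges)) edges <- fes_bin_edges(list(proj), bins)
  ix <- findInterval(proj[, 1], edges$x, rightmost.closed = TRUE)
  iy <- findInterval(proj[, 2], edges$y, rightmost.closed = TRUE)
  nx <- length(edges$x) - 1; ny <- length(edges$y) - 1
  keep <- ix >= 1 & ix <= nx & iy >= 1 & iy <= ny
  counts <- matrix(0L, nx, ny)
  tab <- table(factor(ix[keep], levels = seq_len(nx)),
               factor(iy[keep], levels = seq_len(ny)))
  counts[] <- as.integer(tab)
  if (all(counts == 0)) stop("no projections fall inside the bin edges")
  FF <- matrix(NA_real_, nx, ny)
  pop <- counts >= max(1, min_count)
  if (!any(pop)) stop("no bin reaches min_count = ", min_count)
  FF[pop] <- -kT * log(counts[pop] / max(counts))
  structure(list(F = FF, counts = counts, xedges = edges$x,
                 yedges = edges$y, kT = kT),
            class = "fe_surface")
}

#' @export
print.fe_surface <- function(x, ...) {
  cat(sprintf("free-energy surface: %d x %d bins, %d populated, max F %.2f kT\n",
              nrow(x$F), ncol(x$F), sum(!is.na(x$F)),
              max(x$F, na.rm = TRUE)))
  invisible(x)
}

fes_neighbors <- function(i, j, nx, ny) {
  nb <- rbind(c(i - 1, j), c(i + 1, j), c(i, j - 1), c(i, j + 1))
  nb[nb[, 1] >= 1 & nb[, 1] <= nx & nb[, 2] >= 1 & nb[, 2] <= ny, ,
     drop = FALSE]
}

# steepest-descent target minimum for every populated bin; ties broken by
# row-major order for determinism
descent_targets <- function(FF) {
  nx <- nrow(FF); ny <- ncol(FF)
  target <- matrix(NA_integer_, nx, ny)
  pop <- which(!is.na(FF), arr.ind = TRUE)
  step_to <- matrix(NA_integer_, nx, ny)   # linear index of descent step
  for (r in seq_len(nrow(pop))) {
    i <- pop[r, 1]; j <- pop[r, 2]
    nb <- fes_neighbors(i, j, nx, ny)
    fv <- FF[nb]
    ok <- !is.na(fv) & fv < FF[i, j]
    if (any(ok)) {
      nb <- nb[ok, , drop = FALSE]; fv <- fv[ok]
      b <- which(fv == min(fv))[1]
      step_to[i, j] <- (nb[b, 2] - 1L) * nx + nb[b, 1]
    }
  }
  for (r in seq_len(nrow(pop))) {
    cur <- (pop[r, 2] - 1L) * nx + pop[r, 1]
    start <- cur
    while (!is.na(step_to[cur])) cur <- step_to[cur]
    target[start] <- cur
  }
  target
}

#' Detect basins on a free-energy surface
#'
#' A basin seed is a populated bin strictly lower than all face-adjacent
#' populated bins. Each basin then collects the populated bins within
#' `depth_cutoff` of its minimum that drain to it under steepest descent
#' (so overlapping growth is resolved deterministically). Basins are
#' returned ordered by increasing minimum free energy and labeled
#' "a", "b", ... A perfectly flat surface has no strict minimum and
#' yields no basins.
#'
#' @param surface a [free_energy_surface()]
#' @param depth_cutoff growth depth above each minimum, in kT (default 1)
#' @return list of objects of class `basin`, each with `label`,
#'   `min_bin` (i, j), `min_F`, `members` (k x 2 matrix of bins)
#' @export
find_basins <- function(surface, depth_cutoff = 1) {
  FF <- surface$F
  nx <- nrow(FF); ny <- ncol(FF)
  pop <- which(!is.na(FF), arr.ind = TRUE)
  is_min <- logical(nrow(pop))
  for (r in seq_len(nrow(pop))) {
    i <- pop[r, 1]; j <- pop[r, 2]
    nb <- fes_neighbors(i, j, nx, ny)
    fv <- FF[nb]
    is_min[r] <- all(is.na(fv) | fv > FF[i, j])
  }
  mins <- pop[is_min, , drop = FALSE]
  if (nrow(mins) == 0) return(list())
  target <- descent_targets(FF)
  basins <- lapply(seq_len(nrow(mins)), function(r) {
    i <- unname(mins[r, 1]); j <- unname(mins[r, 2])
    lin <- (j - 1L) * nx + i
    memb <- which(target == lin & FF < FF[i, j] + depth_cutoff)
    memb_ij <- cbind(((memb - 1L) %% nx) + 1L, ((memb - 1L) %/% nx) + 1L)
    structure(list(label = "", min_bin = c(i, j), min_F = FF[i, j],
                   members = memb_ij),
              class = "basin")
  })
  ord <- order(vapply(basins, function(b) b$min_F, 0),
               vapply(basins, function(b) b$min_bin[1], 0),
               vapply(basins, function(b) b$min_bin[2], 0))
  basins <- basins[ord]
  for (k in seq_along(basins)) basins[[k]]$label <- letters[min(k, 26)]
  basins
}

#' @export
print.basin <- function(x, ...) {
  cat(sprintf("basin '%s': minimum F = %.3f kT at bin (%d, %d), %d member bins\n",
              x$label, x$min_F, x$min_bin[1], x$min_bin[2],
              nrow(x$members)))
  invisible(x)
}

bin_centers <- function(edges) (edges[-1] + edges[-length(edges)]) / 2

#' Representative frames of a basin
#'
#' The `m` frames whose projections lie in the basin's member bins and
#' sit closest (Euclidean distance in tIC space) to the center of the
#' basin's minimum bin; ties are broken by (trajectory id, frame index).
#'
#' @param basin a basin from [find_basins()]
#' @param surface the surface the basin came from
#' @param proj n x 2 projection matrix of the pooled frames
#' @param ids data.frame with `traj_id` and `frame` per projection row
#'   (defaults to a single trajectory with sequential frames)
#' @param m number of frames to return
#' @return data.frame of frame references, closest first
#' @export
representative_frames <- function(basin, surface, proj, ids = NULL, m = 1) {
  proj <- as.matrix(proj)
  if (is.null(ids))
    ids <- data.frame(traj_id = "traj1", frame = seq_len(nrow(proj)),
                      stringsAsFactors = FALSE)
  ix <- findInterval(proj[, 1], surface$xedges, rightmost.closed = TRUE)
  iy <- findInterval(proj[, 2], surface$yedges, rightmost.closed = TRUE)
  key <- paste(ix, iy)
  memb <- paste(basin$members[, 1], basin$members[, 2])
  inb <- key %in% memb
  if (!any(inb)) stop("basin contains no frames after filtering")
  ctr <- c(bin_centers(surface$xedges)[basin$min_bin[1]],
           bin_centers(surface$yedges)[basin$min_bin[2]])
  d <- sqrt((proj[, 1] - ctr[1])^2 + (proj[, 2] - ctr[2])^2)
  cand <- which(inb)
  ord <- cand[order(d[cand], ids$traj_id[cand], ids$frame[cand])]
  take <- utils::head(ord, m)
  out <- data.frame(traj_id = ids$traj_id[take], frame = ids$frame[take],
                    tic1 = proj[take, 1], tic2 = proj[take, 2],
                    distance = d[take], stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}
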