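# independent reversible lag-autocorrelation estimator for the 1-D check
sym_autocorr <- function(x, lag) {
  n <- length(x)
  h <- x[1:(n - lag)]; t2 <- x[(1 + lag):n]
  mu <- mean(c(h, t2))
  c0 <- mean(c((h - mu)^2, (t2 - mu)^2))
  ct <- mean((h - mu) * (t2 - mu))
  ct / c0
}

test_that("extract_features flattens aligned coordinates and refuses unaligned input", {
  set.seed(51)
  top <- point_topology(10)
  co <- array(stats::rnorm(5 * 10 * 3), c(5, 10, 3))
  tr <- trajectory(top, co, 0.5)
  expect_error(extract_features(tr, selection(1:10)), "aligned")
  tr$aligned <- TRUE
  f1 <- extract_features(tr, selection(3))
  expect_equal(ncol(f1$X), 3)
  f10 <- extract_features(tr, selection(1:10))
  expect_equal(ncol(f10$X), 30)
  # row t reproduces the frame's selected coordinates
  expect_equal(matrix(f10$X[2, ], ncol = 3, byrow = TRUE),
               frame_coords(tr, 2))
  # and survives an XYZ round-trip of the aligned trajectory
  xf <- tempfile(fileext = ".xyz")
  write_xyz_traj(tr, xf)
  back <- read_xyz_traj(xf, top, 0.5)
  back$aligned <- TRUE
  expect_equal(extract_features(back, selection(1:10))$X, f10$X,
               tolerance = 1e-6)
})

test_that("tICA on white noise has eigenvalues consistent with the simulated null", {
  N <- 10000
  lam_max <- vapply(1:20, function(s) {
    set.seed(520 + s)
    X <- matrix(stats::rnorm(N * 3), N, 3)
    m <- suppressWarnings(tica_fit(feature_matrix(X, frame_interval = 1), 10))
    max(abs(m$eigenvalues))
  }, 0)
  # no spurious slow mode: every null draw stays at the O(1/sqrt(N)) level
  expect_lt(max(lam_max), 10 / sqrt(N))
  expect_lt(mean(lam_max), 5 / sqrt(N))
})

test_that("tICA recovers the OU spectrum; 1-D case equals the lag autocorrelation", {
  # d = 1: single component, eigenvalue = reversible lag autocorrelation
  fm <- gen_ou(ou_spec(t_c = 20, dt = 0.5, n_frames = 5e4, seed = 53))
  m1 <- suppressWarnings(tica_fit(fm, lag_frames = 10))
  expect_equal(m1$eigenvalues, sym_autocorr(fm$X[, 1], 10), tolerance = 1e-6)
  expect_equal(m1$eigenvalues, exp(-10 * 0.5 / 20), tolerance = 0.05)

  # mixed 3-D: eigenvalues near exp(-tau dt / t_c), components C0-orthonormal
  A <- matrix(c(1, 0.5, 0.2, 0, 1, 0.3, 0.1, 0, 1), 3, 3)
  fm3 <- gen_ou(ou_spec(t_c = c(50, 10, 2), dt = 0.5, n_frames = 2e5,
                        mixing = A, seed = 54))
  m3 <- suppressWarnings(tica_fit(fm3, lag_frames = 20))
  expect_equal(m3$eigenvalues, exp(-20 * 0.5 / c(50, 10, 2)),
               tolerance = 0.05)
  expect_equal(t(m3$components) %*% m3$C0 %*% m3$components, diag(3),
               tolerance = 1e-6)
  expect_equal(order(m3$eigenvalues, decreasing = TRUE), 1:3)
  # generalized eigenproblem residual
  for (k in 1:3) {
    r <- m3$Ctau_sym %*% m3$components[, k] -
      m3$eigenvalues[k] * (m3$C0 %*% m3$components[, k])
    expect_lt(sqrt(sum(r^2)), 1e-8 * norm(m3$Ctau_sym, "F"))
  }
})

test_that("tica_fit validates lag and feature dimensions", {
  fm <- feature_matrix(matrix(stats::rnorm(40), 20, 2), replicate_id = "r1")
  expect_error(tica_fit(fm, 20), "r1")
  expect_error(tica_fit(fm, 0), "positive")
  fm2 <- feature_matrix(matrix(stats::rnorm(60), 20, 3))
  expect_error(suppressWarnings(tica_fit(list(fm, fm2), 5)), "dimension")
  # constant feature: rank-deficient beyond regularization
  fmc <- feature_matrix(cbind(stats::rnorm(100), 1), frame_interval = 1)
  m <- suppressWarnings(tica_fit(fmc, 2))   # epsilon rescues the constant dim
  expect_length(m$eigenvalues, 2)
})

test_that("tica_transform is affine, zero at the training mean, and persists bit-for-bit", {
  set.seed(55)
  fm <- gen_ou(ou_spec(t_c = c(10, 3), dt = 1, n_frames = 5000,
                       mixing = matrix(c(1, 0.4, 0.2, 1), 2, 2), seed = 56))
  m <- suppressWarnings(tica_fit(fm, 5))
  expect_equal(as.numeric(tica_transform(m, matrix(m$mean, 1), k = 2)),
               c(0, 0), tolerance = 1e-12)
  a <- matrix(stats::rnorm(2), 1); b <- matrix(stats::rnorm(2), 1)
  expect_equal(tica_transform(m, a) - tica_transform(m, b),
               (a - b) %*% m$components[, 1:2], tolerance = 1e-12)
  expect_error(tica_transform(m, matrix(0, 1, 5)), "dimension")
  # JSON persistence round-trip reproduces projections to near machine
  # precision
  p <- tempfile(fileext = ".json")
  write_tica_model(m, p)
  m2 <- read_tica_model(p)
  expect_equal(tica_transform(m2, fm$X), tica_transform(m, fm$X),
               tolerance = 1e-12)
  # training projections have unit C0-variance per component (reversible
  # frame weighting)
  lagn <- m$lag_frames; n <- nrow(fm$X)
  idx <- c(1:(n - lagn), (1 + lagn):n)
  y <- tica_transform(m, fm$X, k = 2)[idx, ]
  v <- colMeans(sweep(y, 2, colMeans(y))^2)
  expect_equal(unname(v), c(1, 1), tolerance = 1e-2)
})

test_that("implied timescales follow -tau/ln(lambda) with flagged degenerate entries", {
  m <- structure(list(lag_frames = 10L, frame_interval = 10,
                      eigenvalues = c(exp(-1), 1, -0.2), d = 3),
                 class = "tica_model")
  it <- implied_timescales(m)
  expect_equal(it$timescale_ns[1], 100)   # lambda = 1/e at lag 100 ns
  expect_equal(it$status, c("ok", "unit_or_larger", "nonpositive"))
  expect_true(all(is.na(it$timescale_ns[2:3])))
})

test_that("lag_scan returns one row per lag and recovers OU timescales stably", {
  fm <- gen_ou(ou_spec(t_c = 50, dt = 0.5, n_frames = 5e5, seed = 57))
  sc <- suppressWarnings(lag_scan(list(fm), lags = c(10, 20, 50), dims = 1))
  expect_equal(nrow(sc), 3)
  # OU: timescale independent of lag, equal to t_c within sampling error
  expect_true(all(abs(sc$t_1_ns - 50) / 50 < 0.15))
  expect_lt(max(sc$t_1_ns) / min(sc$t_1_ns) - 1, 0.15)
  # single lag reduces to tica_fit
  m <- suppressWarnings(tica_fit(fm, 20))
  expect_equal(sc$lambda_1[2], m$eigenvalues[1], tolerance = 1e-12)
})

test_that("free-energy surface identities hold", {
  # uniform counts -> F identically 0
  set.seed(58)
  xy <- as.matrix(expand.grid(seq(0.5, 9.5), seq(0.5, 9.5)))
  edges <- list(x = seq(0, 10), y = seq(0, 10))
  s <- free_energy_surface(xy, edges = edges)
  expect_true(all(s$F == 0))
  # two bins with counts n and n/e -> dF = 1 kT
  pts <- rbind(matrix(rep(c(0.5, 0.5), 272), ncol = 2, byrow = TRUE),
               matrix(rep(c(1.5, 0.5), 100), ncol = 2, byrow = TRUE))
  s2 <- free_energy_surface(pts, edges = list(x = 0:2, y = 0:1))
  expect_equal(s2$F[2, 1] - s2$F[1, 1], log(272 / 100), tolerance = 1e-12)
  expect_equal(s2$F[1, 1], 0)
  # exp(-F) renormalized over populated bins = empirical bin probabilities
  proj <- matrix(stats::rnorm(4000), 2000, 2)
  s3 <- free_energy_surface(proj, bins = 12)
  p_emp <- s3$counts / sum(s3$counts)
  p_fes <- exp(-s3$F); p_fes[is.na(p_fes)] <- 0
  p_fes <- p_fes / sum(p_fes)
  expect_equal(p_fes, p_emp, tolerance = 1e-12)
  # histogram equals brute-force per-frame binning
  ix <- findInterval(proj[, 1], s3$xedges, rightmost.closed = TRUE)
  iy <- findInterval(proj[, 2], s3$yedges, rightmost.closed = TRUE)
  brute <- matrix(0L, 12, 12)
  for (i in seq_len(nrow(proj))) brute[ix[i], iy[i]] <- brute[ix[i], iy[i]] + 1L
  expect_equal(s3$counts, brute)
  # min_count masks sparse bins
  s4 <- free_energy_surface(proj, bins = 12, min_count = 5)
  expect_true(all(is.na(s4$F[s3$counts < 5])))
})

test_that("shared axes make combined counts the sum of per-condition counts", {
  set.seed(59)
  pa <- matrix(stats::rnorm(1000, -1), 500, 2)
  pb <- matrix(stats::rnorm(1000, +1), 500, 2)
  edges <- fes_bin_edges(list(pa, pb), bins = 20)
  sa <- free_energy_surface(pa, edges = edges)
  sb <- free_energy_surface(pb, edges = edges)
  sc <- free_energy_surface(rbind(pa, pb), edges = edges)
  expect_equal(sa$counts + sb$counts, sc$counts)
  expect_equal(sum(sa$counts), 500)   # nothing falls off the shared axes
})

test_that("find_basins detects wells, respects the depth cutoff and tie convention", {
  # single-well paraboloid -> exactly one basin at the apex
  x <- seq(-2, 2, length.out = 21)
  FF <- outer(x, x, function(a, b) a^2 + b^2)
  counts <- matrix(1000L, 21, 21)  # populated everywhere
  surf <- structure(list(F = FF, counts = counts, xedges = seq(0, 21),
                         yedges = seq(0, 21), kT = 1), class = "fe_surface")
  b1 <- find_basins(surf, depth_cutoff = 1)
  expect_length(b1, 1)
  expect_equal(b1[[1]]$min_bin, c(11, 11))
  # members: all bins within 1 kT draining to the apex
  expect_true(all(FF[b1[[1]]$members] < 1))
  # double well with a barrier above the cutoff -> two basins, ordered by depth
  g <- seq(-1.5, 1.5, length.out = 31)
  F2 <- outer(g, g, function(a, b) 2 * (a^2 - 1)^2 + 0.5 * b^2 + 0.2 * a)
  F2 <- F2 - min(F2)
  surf2 <- structure(list(F = F2, counts = matrix(1000L, 31, 31),
                          xedges = seq(0, 31), yedges = seq(0, 31), kT = 1),
                     class = "fe_surface")
  b2 <- find_basins(surf2, depth_cutoff = 1)
  expect_length(b2, 2)
  expect_lt(b2[[1]]$min_F, b2[[2]]$min_F)
  expect_equal(vapply(b2, function(b) b$label, ""), c("a", "b"))
  # member bins stay on their own side of the barrier
  expect_true(all(b2[[1]]$members[, 1] < 16))  # the +0.2a tilt favours a < 0
  # flat surface -> no strict minimum, no basins
  surf3 <- structure(list(F = matrix(0, 5, 5), counts = matrix(10L, 5, 5),
                          xedges = seq(0, 5), yedges = seq(0, 5), kT = 1),
                     class = "fe_surface")
  expect_length(find_basins(surf3, 1), 0)
})

test_that("representative frames lie in the basin and are ordered by distance", {
  set.seed(60)
  proj <- rbind(matrix(stats::rnorm(400, -2, 0.3), 200, 2),
                matrix(stats::rnorm(400, +2, 0.3), 200, 2))
  ids <- data.frame(traj_id = rep(c("p1", "p2"), each = 200),
                    frame = rep(1:200, 2), stringsAsFactors = FALSE)
  s <- free_energy_surface(proj, bins = 15)
  basins <- find_basins(s, depth_cutoff = 2)
  expect_gte(length(basins), 2)
  reps <- representative_frames(basins[[1]], s, proj, ids, m = 5)
  expect_equal(nrow(reps), 5)
  expect_true(all(diff(reps$distance) >= 0))
  # containment: every representative's bin is a member bin
  memb <- paste(basins[[1]]$members[, 1], basins[[1]]$members[, 2])
  ix <- findInterval(reps$tic1, s$xedges, rightmost.closed = TRUE)
  iy <- findInterval(reps$tic2, s$yedges, rightmost.closed = TRUE)
  expect_true(all(paste(ix, iy) %in% memb))
  # m larger than membership returns all members
  small <- representative_frames(basins[[1]], s, proj, ids, m = 1e6)
  expect_lte(nrow(small), 400)
  expect_gt(nrow(small), 0)
})
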