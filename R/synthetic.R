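# Seeded synthetic-trajectory generators.
#
# These supply ground truth for every analysis stage: an exact
# Ornstein-Uhlenbeck discretization with a known slow-mode spectrum, an
# overdamped double-well Langevin walker with known state labels, and a
# "toy transporter" that emulates the statistical structure of the study
# trajectories (two conditions, gated ligand escape toward a lower
# residue cluster, condition-dependent hydration) without any pretense of
# physical realism. All generators are bit-reproducible given their spec
# and seed, and leave the caller's RNG state untouched.

with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit(if (had) assign(".Random.seed", old, envir = globalenv())
          else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
            rm(".Random.seed", envir = globalenv()))
  set.seed(seed)
  expr
}

#' Ornstein-Uhlenbeck process specification
#'
#' @param t_c correlation time(s) in ns; a vector gives one independent
#'   component per entry
#' @param sd stationary standard deviation(s)
#' @param dt frame interval in ns
#' @param n_frames number of frames
#' @param mixing optional d x d matrix mixing the latent components into
#'   the observed features
#' @param seed RNG seed
#' @return object of class `ou_spec`
#' @export
ou_spec <- function(t_c, sd = 1, dt = 0.5, n_frames = 1000,
                    mixing = NULL, seed = 1) {
  if (any(t_c <= 0)) stop("correlation times must be positive")
  if (dt <= 0) stop("dt must be positive")
  d <- length(t_c)
  sd <- rep_len(sd, d)
  if (!is.null(mixing) && !all(dim(as.matrix(mixing)) == d))
    stop("mixing matrix must be ", d, " x ", d)
  structure(list(t_c = t_c, sd = sd, dt = dt,
                 n_frames = as.integer(n_frames),
                 mixing = mixing, seed = as.integer(seed)),
            class = "ou_spec")
}

#' Generate an Ornstein-Uhlenbeck feature trajectory
#'
#' Exact discretization x_{t+1} = alpha x_t + sqrt(1 - alpha^2) sd xi
#' with alpha = exp(-dt / t_c), which preserves the stationary variance
#' at any step size. Component i relaxes with correlation time t_c[i],
#' so its lag-tau autocorrelation is exp(-tau dt / t_c[i]) — the known
#' spectrum tICA should recover. An optional mixing matrix hides the
#' latent components in correlated observables.
#'
#' @param spec an [ou_spec()]
#' @return a [feature_matrix()]; the unmixed latent series is attached as
#'   attribute "latent"
#' @export
gen_ou <- function(spec) {
  stopifnot(inherits(spec, "ou_spec"))
  d <- length(spec$t_c)
  with_seed(spec$seed, {
    S <- matrix(0, spec$n_frames, d)
    for (k in seq_len(d)) {
      a <- exp(-spec$dt / spec$t_c[k])
      innov <- stats::rnorm(spec$n_frames, 0, sqrt(1 - a^2) * spec$sd[k])
      x0 <- stats::rnorm(1, 0, spec$sd[k])
      S[, k] <- as.numeric(stats::filter(innov, a, method = "recursive",
                                         init = x0))
    }
    X <- if (is.null(spec$mixing)) S else S %*% t(as.matrix(spec$mixing))
    fm <- feature_matrix(X, feature_label = "ou",
                         frame_interval = spec$dt,
                         replicate_id = paste0("ou_seed", spec$seed))
    attr(fm, "latent") <- S
    fm
  })
}

#' Double-well Langevin specification
#'
#' @param barrier barrier height b in kT; the potential is
#'   U(x) = b (x^2 - 1)^2, with wells at x = -1 and x = +1
#' @param gamma friction coefficient
#' @param dt integrator step (must satisfy dt <= gamma / (8 b) for
#'   stability)
#' @param n_frames number of saved frames
#' @param stride integrator steps per saved frame (default 20); saving
#'   sparser than the integrator step mirrors MD practice and puts the
#'   fast intra-well relaxation well below one frame
#' @param seed RNG seed
#' @return object of class `double_well_spec`
#' @export
double_well_spec <- function(barrier = 4, gamma = 1, dt = 0.01,
                             n_frames = 1e5, stride = 20, seed = 1) {
  if (barrier <= 0) stop("barrier height must be positive")
  if (dt > gamma / (8 * barrier))
    stop("unstable step: dt must be <= gamma / (8 * barrier) = ",
         signif(gamma / (8 * barrier), 3))
  if (stride < 1) stop("stride must be >= 1")
  structure(list(barrier = barrier, gamma = gamma, dt = dt,
                 n_frames = as.integer(n_frames), stride = as.integer(stride),
                 seed = as.integer(seed)),
            class = "double_well_spec")
}

#' Generate an overdamped double-well Langevin trajectory
#'
#' Euler-Maruyama integration of
#' x <- x - dt U'(x) / gamma + sqrt(2 dt / gamma) xi  (kT = 1),
#' with U(x) = b (x^2 - 1)^2, saving every `stride`-th step. The
#' ground-truth metastable state label is sign(x) at the saved frames.
#'
#' @param spec a [double_well_spec()]
#' @return list with `x` (saved series), `state` (sign labels),
#'   `frame_dt` (time per saved frame, = dt * stride), `spec`
#' @export
gen_double_well <- function(spec) {
  stopifnot(inherits(spec, "double_well_spec"))
  b <- spec$barrier; g <- spec$gamma; dt <- spec$dt
  n <- spec$n_frames; stride <- spec$stride
  with_seed(spec$seed, {
    nsteps <- n * stride
    noise <- stats::rnorm(nsteps, 0, sqrt(2 * dt / g))
    x <- numeric(n)
    xt <- 1
    k <- 0L
    for (t in seq_len(nsteps)) {
      xt <- xt - dt * 4 * b * xt * (xt^2 - 1) / g + noise[t]
      if (t %% stride == 0L) {
        k <- k + 1L
        x[k] <- xt
      }
    }
    list(x = x, state = sign(x), frame_dt = dt * stride, spec = spec)
  })
}

#' Toy-transporter specification
#'
#' Defines the synthetic two-condition system: a static pseudo-protein
#' with an upper binding pocket (residues Y51, S53, W55, A56, C74, Y75),
#' a lower pocket along the exit channel (F248, S251, H257, F406), a
#' flexible helix-break region, a Na2-site lysine (K196), one histidine
#' ligand, and ideal-gas waters. A telegraph-process "gate" controls
#' both ligand escape toward the lower pocket and water access to the
#' core. Under "protonated" defaults the gate never opens (rigid,
#' dehydrated core); under "deprotonated" defaults it opens and closes
#' on the 100-200 ns scale, the break region is more flexible, and the
#' ligand intermittently occupies the lower pocket.
#'
#' @param condition "protonated" or "deprotonated"
#' @param k_open,k_close gate opening/closing rates per ns; defaults
#'   depend on condition (protonated: 0 and 0.05; deprotonated: 0.01 and
#'   0.002, i.e. ~100 ns closed and ~500 ns open dwell times, so the
#'   core hydrates within the first half of a 1000 ns replicate and
#'   stays hydrated most of the time thereafter)
#' @param n_waters number of water molecules (default 200)
#' @param box box dimensions in Angstrom (default 40 x 40 x 60)
#' @param n_frames frames per replicate (default 2000)
#' @param frame_interval ns per frame (default 0.5, i.e. 1000 ns total)
#' @param n_replicates replicates to generate (default 5)
#' @param ligand_sd ligand positional fluctuation in Angstrom (default
#'   1.0 protonated, 1.8 deprotonated)
#' @param break_sd break-region fluctuation in Angstrom (default 0.5
#'   protonated, 1.2 deprotonated)
#' @param seed base seed; replicate r uses seed + r - 1
#' @return object of class `toy_transporter_spec`
#' @export
toy_transporter_spec <- function(condition = c("protonated", "deprotonated"),
                                 k_open = NULL, k_close = NULL,
                                 n_waters = 200, box = c(40, 40, 60),
                                 n_frames = 2000, frame_interval = 0.5,
                                 n_replicates = 5,
                                 ligand_sd = NULL, break_sd = NULL,
                                 seed = 1) {
  condition <- match.arg(condition)
  deprot <- condition == "deprotonated"
  if (is.null(k_open)) k_open <- if (deprot) 0.01 else 0
  if (is.null(k_close)) k_close <- if (deprot) 0.002 else 0.05
  if (is.null(ligand_sd)) ligand_sd <- if (deprot) 1.8 else 1.0
  if (is.null(break_sd)) break_sd <- if (deprot) 1.2 else 0.5
  if (k_open < 0 || k_close < 0) stop("rates must be non-negative")
  pocket <- c(box[1] / 2, box[2] / 2, 35)
  lower <- c(box[1] / 2, box[2] / 2, 20)
  if (any(pocket > box) || any(lower > box))
    stop("pocket geometry must nest inside the box")
  structure(list(condition = condition, k_open = k_open, k_close = k_close,
                 n_waters = as.integer(n_waters), box = box,
                 n_frames = as.integer(n_frames),
                 frame_interval = frame_interval,
                 n_replicates = as.integer(n_replicates),
                 ligand_sd = ligand_sd, break_sd = break_sd,
                 pocket_center = pocket, lower_center = lower,
                 exclusion_radius = 10, ligand_tc = 25, break_tc = 10,
                 water_step_sd = 1.0, seed = as.integer(seed)),
            class = "toy_transporter_spec")
}

toy_protein_layout <- function(spec) {
  P <- spec$pocket_center; L <- spec$lower_center
  ring <- function(center, resids, resnames, radii = c(5.5, 4.4, 3.4)) {
    n <- length(resids)
    ang <- 2 * pi * (seq_len(n) - 1) / n
    do.call(rbind, lapply(seq_len(n), function(i) {
      u <- c(cos(ang[i]), sin(ang[i]), 0)
      data.frame(name = c("CA", "CB", "CG"), element = "C",
                 resname = resnames[i], resid = resids[i], chain = "A",
                 x = center[1] + radii * u[1],
                 y = center[2] + radii * u[2],
                 z = center[3] + c(1, 0.5, 0) * (i %% 2),
                 stringsAsFactors = FALSE)
    }))
  }
  upper <- ring(P, c(51, 53, 55, 56, 74, 75),
                c("TYR", "SER", "TRP", "ALA", "CYS", "TYR"))
  lowerres <- ring(L, c(248, 251, 257, 406),
                   c("PHE", "SER", "HIS", "PHE"))
  brk <- do.call(rbind, lapply(0:2, function(i)
    data.frame(name = c("CA", "CB"), element = "C", resname = "GLY",
               resid = 190 + i, chain = "A",
               x = P[1] - 7, y = P[2] - 3 + 3 * i, z = P[3] - 5,
               stringsAsFactors = FALSE)))
  k196 <- data.frame(name = c("CA", "NZ"), element = c("C", "N"),
                     resname = "LYS", resid = 196, chain = "A",
                     x = P[1], y = P[2] + 1, z = c(33, 34),
                     stringsAsFactors = FALSE)
  lig <- data.frame(name = c("CA", "CB", "CG", "ND1", "NE2"),
                    element = c("C", "C", "C", "N", "N"),
                    resname = "HIS", resid = 999, chain = "A",
                    x = P[1] + c(0, 1.2, -0.9, 0.5, -0.5),
                    y = P[2] + c(0, 0.3, 0.8, -1.0, -0.6),
                    z = P[3] + c(0, 0.8, -0.6, 0.4, 1.0),
                    stringsAsFactors = FALSE)
  list(protein = rbind(brk, k196, upper, lowerres), ligand = lig)
}

random_rotation_small <- function(sd_angle = 0.15) {
  ax <- stats::rnorm(3); ax <- ax / sqrt(sum(ax^2))
  th <- stats::rnorm(1, 0, sd_angle)
  K <- matrix(c(0, -ax[3], ax[2], ax[3], 0, -ax[1], -ax[2], ax[1], 0),
              3, 3, byrow = TRUE)
  diag(3) + sin(th) * K + (1 - cos(th)) * (K %*% K)
}

#' Generate toy-transporter replicates
#'
#' Per frame, the gate state follows a telegraph process; the ligand
#' relaxes (OU, correlation time ~25 ns) toward the upper pocket while
#' the gate is closed and toward the lower pocket while it is open; the
#' break region fluctuates with condition-dependent amplitude plus a
#' shift while the gate is open; waters random-walk in the box but are
#' excluded from a sphere around the pocket while the gate is closed.
#' Every frame finally receives a small random rigid-body rotation and
#' translation of the whole system, so alignment is exercised. Waters
#' carry 3-atom rigid geometry so oxygen-counting conventions are
#' exercised too.
#'
#' @param spec a [toy_transporter_spec()]
#' @return list of replicates; each has `trajectory` (unaligned),
#'   `reference` (the internal-frame coordinates, the natural
#'   post-equilibration reference) and `truth` (data.frame: frame, time,
#'   gate_open, ligand z in the internal frame)
#' @export
gen_toy_transporter <- function(spec) {
  stopifnot(inherits(spec, "toy_transporter_spec"))
  layout <- toy_protein_layout(spec)
  prot <- layout$protein; lig <- layout$ligand
  nw <- spec$n_waters
  water_atoms <- do.call(rbind, lapply(seq_len(nw), function(i)
    data.frame(name = c("O", "H1", "H2"), element = c("O", "H", "H"),
               resname = "HOH", resid = 1000 + i, chain = "W",
               x = 0, y = 0, z = 0, stringsAsFactors = FALSE)))
  atoms <- rbind(prot, lig, water_atoms)
  atoms$serial <- seq_len(nrow(atoms))
  atoms$occupancy <- 1
  atoms$bfactor <- 0
  top <- topology(atoms[, c("serial", "name", "element", "resname",
                            "resid", "chain", "occupancy", "bfactor")])
  base <- as.matrix(atoms[, c("x", "y", "z")])
  np <- nrow(prot); nl <- nrow(lig)
  lig_rows <- np + seq_len(nl)
  brk_rows <- which(prot$resid %in% 190:192)
  wO_rows <- np + nl + 3 * (seq_len(nw) - 1) + 1
  h1_off <- c(0.9572, 0, 0); h2_off <- c(-0.2399, 0.9266, 0)

  P <- spec$pocket_center; L <- spec$lower_center
  a_lig <- exp(-spec$frame_interval / spec$ligand_tc)
  a_brk <- exp(-spec$frame_interval / spec$break_tc)
  p_open <- 1 - exp(-spec$k_open * spec$frame_interval)
  p_close <- 1 - exp(-spec$k_close * spec$frame_interval)
  r2excl <- spec$exclusion_radius^2

  lapply(seq_len(spec$n_replicates), function(rep) {
    with_seed(spec$seed + rep - 1L, {
      nf <- spec$n_frames
      coords <- array(0, c(nf, nrow(base), 3))
      truth <- data.frame(frame = seq_len(nf),
                          time = (seq_len(nf) - 1) * spec$frame_interval,
                          gate_open = FALSE, ligand_z = 0)
      # waters start uniform outside the (closed-gate) exclusion sphere
      wpos <- matrix(0, nw, 3)
      placed <- 0
      while (placed < nw) {
        cand <- c(stats::runif(1, 0, spec$box[1]),
                  stats::runif(1, 0, spec$box[2]),
                  stats::runif(1, 0, spec$box[3]))
        if (sum((cand - P)^2) > r2excl) {
          placed <- placed + 1
          wpos[placed, ] <- cand
        }
      }
      gate_open <- FALSE
      lig_center <- P
      brk_disp <- c(0, 0, 0)
      for (f in seq_len(nf)) {
        gate_open <- if (gate_open) stats::runif(1) >= p_close
                     else stats::runif(1) < p_open
        target <- if (gate_open) L else P
        sd_innov <- sqrt(1 - a_lig^2) * spec$ligand_sd
        lig_center <- target + a_lig * (lig_center - target) +
          stats::rnorm(3, 0, sd_innov)
        brk_target <- if (gate_open) c(0, 0, -2.5) else c(0, 0, 0)
        brk_disp <- brk_target + a_brk * (brk_disp - brk_target) +
          stats::rnorm(3, 0, sqrt(1 - a_brk^2) * spec$break_sd)

        wpos <- wpos + matrix(stats::rnorm(3 * nw, 0, spec$water_step_sd),
                              nw, 3)
        for (d in 1:3) {    # reflecting box walls
          wpos[, d] <- abs(wpos[, d])
          over <- wpos[, d] > spec$box[d]
          wpos[over, d] <- 2 * spec$box[d] - wpos[over, d]
          wpos[, d] <- pmin(pmax(wpos[, d], 0), spec$box[d])
        }
        if (!gate_open) {   # mirror-reflect waters off the pocket sphere
          dv <- sweep(wpos, 2, P)
          d2 <- rowSums(dv^2)
          inside <- d2 < r2excl
          if (any(inside)) {
            dn <- pmax(sqrt(d2[inside]), spec$exclusion_radius / 2)
            rnew <- 2 * spec$exclusion_radius - dn
            wpos[inside, ] <- rep(P, each = sum(inside)) +
              dv[inside, , drop = FALSE] * (rnew / dn)
          }
        }

        fr <- base
        fr[seq_len(np), ] <- base[seq_len(np), ] +
          matrix(stats::rnorm(3 * np, 0, 0.25), np, 3)
        fr[brk_rows, ] <- sweep(fr[brk_rows, , drop = FALSE], 2, brk_disp, `+`)
        fr[lig_rows, ] <- sweep(base[lig_rows, , drop = FALSE], 2,
                                lig_center - P, `+`) +
          matrix(stats::rnorm(3 * nl, 0, 0.2), nl, 3)
        fr[wO_rows, ] <- wpos
        fr[wO_rows + 1, ] <- sweep(wpos, 2, h1_off, `+`)
        fr[wO_rows + 2, ] <- sweep(wpos, 2, h2_off, `+`)

        R <- random_rotation_small()
        shift <- stats::rnorm(3, 0, 2)
        coords[f, , ] <- sweep(fr %*% t(R), 2, shift, `+`)
        truth$gate_open[f] <- gate_open
        truth$ligand_z[f] <- lig_center[3]
      }
      list(trajectory = trajectory(top, coords, spec$frame_interval,
                                   condition_label = spec$condition,
                                   replicate_id = sprintf("%s_rep%d",
                                                          spec$condition, rep)),
           reference = base, truth = truth)
    })
  })
}

#' Ideal-gas water trajectory
#'
#' Water molecules placed independently and uniformly in a box at every
#' frame (no dynamics), plus one probe atom fixed at the box center.
#' Used to validate shell-count statistics against the analytic
#' expectation N (4/3) pi r^3 / V.
#'
#' @param n_waters number of water molecules
#' @param box box dimensions in Angstrom
#' @param n_frames number of frames
#' @param frame_interval ns per frame
#' @param seed RNG seed
#' @return a [trajectory()] whose first atom is the probe ("CA" of
#'   residue 1)
#' @export
gen_ideal_gas_waters <- function(n_waters = 200, box = c(40, 40, 60),
                                 n_frames = 300, frame_interval = 0.5,
                                 seed = 1) {
  probe <- data.frame(name = "CA", element = "C", resname = "GLY",
                      resid = 1, chain = "A", stringsAsFactors = FALSE)
  waters <- do.call(rbind, lapply(seq_len(n_waters), function(i)
    data.frame(name = c("O", "H1", "H2"), element = c("O", "H", "H"),
               resname = "HOH", resid = 100 + i, chain = "W",
               stringsAsFactors = FALSE)))
  atoms <- rbind(probe, waters)
  atoms$serial <- seq_len(nrow(atoms))
  atoms$occupancy <- 1; atoms$bfactor <- 0
  top <- topology(atoms[, c("serial", "name", "element", "resname",
                            "resid", "chain", "occupancy", "bfactor")])
  ctr <- box / 2
  na <- nrow(atoms)
  h1_off <- c(0.9572, 0, 0); h2_off <- c(-0.2399, 0.9266, 0)
  with_seed(seed, {
    coords <- array(0, c(n_frames, na, 3))
    for (f in seq_len(n_frames)) {
      o <- cbind(stats::runif(n_waters, 0, box[1]),
                 stats::runif(n_waters, 0, box[2]),
                 stats::runif(n_waters, 0, box[3]))
      m <- matrix(0, na, 3)
      m[1, ] <- ctr
      rows <- 1 + 3 * (seq_len(n_waters) - 1) + 1
      m[rows, ] <- o
      m[rows + 1, ] <- sweep(o, 2, h1_off, `+`)
      m[rows + 2, ] <- sweep(o, 2, h2_off, `+`)
      coords[f, , ] <- m
    }
    trajectory(top, coords, frame_interval, aligned = TRUE)
  })
}
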