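# Shared fixtures and independent oracles, built in code at test time.

mini_pdb_path <- function() {
  system.file("extdata", "mini.pdb", package = "transportdyn")
}

# tiny hand-built topology: n "CA" pseudo-atoms, one residue each
point_topology <- function(n, resname = "GLY", chain = "A") {
  topology(data.frame(
    serial = seq_len(n), name = "CA", element = "C",
    resname = resname, resid = seq_len(n), chain = chain,
    occupancy = 1, bfactor = 0, stringsAsFactors = FALSE))
}

# uniform random proper rotation via unit quaternion
random_rotation <- function() {
  q <- stats::rnorm(4)
  q <- q / sqrt(sum(q^2))
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
           2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
           2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)),
         3, 3, byrow = TRUE)
}

# brute-force minimum RMSD over n_rot random proper rotations of the
# mean-centered mobile cloud (independent of the SVD path):
# ||A0 R' - B0||^2 = ||A0||^2 + ||B0||^2 - 2 tr(R A0' B0)
brute_min_rmsd <- function(mobile, reference, n_rot = 1e4) {
  A0 <- sweep(mobile, 2, colMeans(mobile))
  B0 <- sweep(reference, 2, colMeans(reference))
  ssa <- sum(A0^2); ssb <- sum(B0^2)
  M <- crossprod(A0, B0)                    # A0' B0
  m9 <- as.vector(t(M))                     # so sum(R * t(M)) = tr(R M)
  Rs <- t(vapply(seq_len(n_rot), function(i) as.vector(random_rotation()),
                 numeric(9)))
  costs <- ssa + ssb - 2 * (Rs %*% m9)
  sqrt(max(min(costs), 0) / nrow(mobile))
}

# fortran-record DCD writer used to probe the reader's endianness
# handling; independent code path from the package reader
write_dcd_fixture <- function(coords, path, endian = "little",
                              nset = dim(coords)[1]) {
  con <- file(path, "wb")
  on.exit(close(con))
  rec <- function(writer, nbytes) {
    writeBin(as.integer(nbytes), con, size = 4, endian = endian)
    writer()
    writeBin(as.integer(nbytes), con, size = 4, endian = endian)
  }
  nf <- dim(coords)[1]; na <- dim(coords)[2]
  rec(function() {
    writeChar("CORD", con, 4, eos = NULL)
    writeBin(as.integer(c(nset, 0, 1, rep(0, 16), 24)), con, size = 4,
             endian = endian)
  }, 84)
  rec(function() {
    writeBin(1L, con, size = 4, endian = endian)
    writeChar(sprintf("%-80s", "synthetic fixture"), con, 80, eos = NULL)
  }, 84)
  rec(function() writeBin(as.integer(na), con, size = 4, endian = endian), 4)
  for (f in seq_len(nf)) for (d in 1:3)
    rec(function() writeBin(as.numeric(coords[f, , d]), con, size = 4,
                            endian = endian), 4 * na)
  invisible(path)
}

python_available <- function(module) {
  nzchar(Sys.which("python")) &&
    system2("python", c("-c", shQuote(paste0("import ", module))),
            stdout = FALSE, stderr = FALSE) == 0
}

# cross-tool DCD oracle: mdtraj writes the DCD from a PDB + plain-text
# coordinate table
mdtraj_write_dcd <- function(pdb_path, coords, dcd_path) {
  txt <- tempfile(fileext = ".tsv")
  nf <- dim(coords)[1]
  flat <- do.call(rbind, lapply(seq_len(nf), function(f)
    matrix(coords[f, , ], ncol = 3)))
  utils::write.table(flat, txt, row.names = FALSE, col.names = FALSE)
  script <- tempfile(fileext = ".py")
  writeLines(c(
    "import sys, numpy as np, mdtraj as md",
    "pdb, txt, out, nf = sys.argv[1], sys.argv[2], sys.argv[3], int(sys.argv[4])",
    "xyz = np.loadtxt(txt).reshape(nf, -1, 3) / 10.0",  # A -> nm
    "top = md.load(pdb).topology",
    "md.Trajectory(xyz, top).save_dcd(out)"), script)
  status <- system2("python", c(script, pdb_path, txt, dcd_path, nf))
  stopifnot(status == 0)
  invisible(dcd_path)
}

# independent OpenDX reader (gridData ships with MDAnalysis)
griddata_read_dx <- function(dx_path) {
  out <- tempfile(fileext = ".txt")
  script <- tempfile(fileext = ".py")
  writeLines(c(
    "import sys, numpy as np",
    "from gridData import Grid",
    "g = Grid(sys.argv[1])",
    "delta = np.diag(g.delta) if getattr(g.delta, 'ndim', 1) == 2 else np.asarray(g.delta)",
    "with open(sys.argv[2], 'w') as fh:",
    "    fh.write(' '.join(map(repr, np.asarray(g.origin).tolist())) + '\\n')",
    "    fh.write(' '.join(map(repr, delta.tolist())) + '\\n')",
    "    fh.write(' '.join(map(str, g.grid.shape)) + '\\n')",
    "    fh.write(' '.join(map(repr, g.grid.ravel().tolist())) + '\\n')"), script)
  status <- system2("python", c(script, dx_path, out))
  stopifnot(status == 0)
  lines <- readLines(out)
  list(origin = as.numeric(strsplit(lines[1], " ")[[1]]),
       delta = as.numeric(strsplit(lines[2], " ")[[1]]),
       shape = as.integer(strsplit(lines[3], " ")[[1]]),
       values = as.numeric(strsplit(lines[4], " ")[[1]]))
}

# probe atom (row 1) at a fixed point plus controllable waters
water_box_traj <- function(water_pos_per_frame, probe = c(0, 0, 0),
                           frame_interval = 1) {
  nw <- ncol(water_pos_per_frame[[1]])  # waters given as 3 x n matrices
  probe_atoms <- data.frame(name = "CA", element = "C", resname = "GLY",
                            resid = 1, chain = "A", stringsAsFactors = FALSE)
  waters <- do.call(rbind, lapply(seq_len(nw), function(i)
    data.frame(name = c("O", "H1", "H2"), element = c("O", "H", "H"),
               resname = "HOH", resid = 10 + i, chain = "W",
               stringsAsFactors = FALSE)))
  a <- rbind(probe_atoms, waters)
  a$serial <- seq_len(nrow(a)); a$occupancy <- 1; a$bfactor <- 0
  top <- topology(a[, c("serial", "name", "element", "resname", "resid",
                        "chain", "occupancy", "bfactor")])
  nf <- length(water_pos_per_frame)
  co <- array(0, c(nf, nrow(a), 3))
  for (f in seq_len(nf)) {
    co[f, 1, ] <- probe
    o <- t(water_pos_per_frame[[f]])
    rows <- 1 + 3 * (seq_len(nw) - 1) + 1
    co[f, rows, ] <- o
    co[f, rows + 1, ] <- sweep(o, 2, c(0.96, 0, 0), `+`)
    co[f, rows + 2, ] <- sweep(o, 2, c(-0.24, 0.93, 0), `+`)
  }
  trajectory(top, co, frame_interval, aligned = TRUE)
}

# --- end-to-end toy-transporter analysis, shared by the acceptance and
# --- invariant tests; cached per session since it takes ~1 min
.toy_cache <- new.env(parent = emptyenv())

toy_pipeline <- function(seed_prot = 101, seed_deprot = 201) {
  key <- paste0("s", seed_prot, "_", seed_deprot)
  if (!is.null(.toy_cache[[key]])) return(.toy_cache[[key]])
  conds <- list(
    protonated = gen_toy_transporter(
      toy_transporter_spec("protonated", seed = seed_prot)),
    deprotonated = gen_toy_transporter(
      toy_transporter_spec("deprotonated", seed = seed_deprot)))
  top <- conds$protonated[[1]]$trajectory$topology
  fit_sel <- select_atoms(top, "backbone and resid 1..500")
  lig_sel <- select_atoms(top, "resid 999 and heavy")
  shell <- shell_spec(select_atoms(top, "resid 196 and name CA"), "1nm")
  res <- residue_list(top)
  res <- res[res$resid != 999, , drop = FALSE]

  an <- lapply(conds, function(reps) lapply(reps, function(r) {
    tr <- align_trajectory(r$trajectory, r$reference, fit_sel)
    list(traj = tr, ref = r$reference, truth = r$truth,
         contacts = contact_frequencies(tr, lig_sel, res, cutoff = 3.5),
         wc = water_count_series(tr, shell))
  }))
  tabs <- lapply(names(an), function(cn)
    contact_table(lapply(an[[cn]], `[[`, "contacts"),
                  vapply(an[[cn]], function(x) n_frames(x$traj), 0L),
                  condition_label = cn))
  names(tabs) <- names(an)

  feats <- unlist(lapply(an, function(a)
    lapply(a, function(x) extract_features(x$traj, lig_sel, "ligand_coords"))),
    recursive = FALSE)
  model <- tica_fit(feats, lag_frames = 200)   # 100 ns at 0.5 ns/frame
  proj <- lapply(an, function(a) do.call(rbind, lapply(a, function(x)
    tica_transform(model, extract_features(x$traj, lig_sel, "ligand_coords")))))
  edges <- fes_bin_edges(proj, bins = 16)
  surfs <- lapply(proj, free_energy_surface, edges = edges, min_count = 5)
  basins <- lapply(surfs, find_basins, depth_cutoff = 1)

  out <- list(conds = conds, an = an, tabs = tabs, top = top,
              fit_sel = fit_sel, lig_sel = lig_sel, shell = shell,
              model = model, proj = proj, edges = edges, surfs = surfs,
              basins = basins)
  .toy_cache[[key]] <- out
  out
}
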