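test_that("read_pdb parses fixed-column records, infers elements, applies altloc policy", {
  one <- tempfile(fileext = ".pdb")
  writeLines(c(
    "ATOM      1  CA  GLY A   1       1.000   2.000   3.000  1.00  0.00",
    "END"), one)
  p <- read_pdb(one)
  expect_equal(n_atoms(p$topology), 1)
  expect_equal(p$coords[1, ], c(1, 2, 3))
  # element column is blank: " CA " (indented) is carbon, not calcium
  expect_equal(p$topology$atoms$element, "C")

  m <- suppressWarnings(read_pdb(mini_pdb_path()))
  # altloc B of the alanine CB is dropped, A kept
  expect_warning(read_pdb(mini_pdb_path()), "alternate-location")
  expect_equal(n_atoms(m$topology), 11)
  expect_equal(sum(m$topology$atoms$name == "CB"), 1)
  # water mask selects exactly the 2 HOH oxygens + 4 hydrogens
  expect_equal(sum(mask_water(m$topology)), 6)
  expect_equal(
    m$topology$atoms$element[mask_water(m$topology)],
    c("O", "H", "H", "O", "H", "H"))
  expect_equal(m$topology$atoms$bfactor[1], 10)
})

test_that("read_pdb errors name the offending line; zero atoms refused", {
  bad <- tempfile(fileext = ".pdb")
  writeLines(c(
    "ATOM      1  CA  GLY A   1       1.000   2.000   3.000  1.00  0.00",
    "ATOM      2  CA  GLY A   2       1.000   bad..   3.000  1.00  0.00"),
    bad)
  expect_error(read_pdb(bad), "line 2")
  empty <- tempfile(fileext = ".pdb")
  writeLines("REMARK nothing here", empty)
  expect_error(read_pdb(empty), "no ATOM/HETATM")
  expect_error(read_pdb(tempfile()), "no such file")
})

test_that("PDB round-trip preserves metadata and coordinates; overflow refused", {
  m <- suppressWarnings(read_pdb(mini_pdb_path()))
  out1 <- tempfile(fileext = ".pdb")
  write_pdb(m$topology, m$coords, out1)
  back <- read_pdb(out1)
  expect_equal(back$topology$atoms$name, m$topology$atoms$name)
  expect_equal(back$topology$atoms$resname, m$topology$atoms$resname)
  expect_equal(back$topology$atoms$resid, m$topology$atoms$resid)
  expect_equal(back$topology$atoms$element, m$topology$atoms$element)
  expect_equal(back$coords, m$coords, tolerance = 1e-3)
  # second write is byte-stable
  out2 <- tempfile(fileext = ".pdb")
  write_pdb(back$topology, back$coords, out2)
  expect_identical(readLines(out1), readLines(out2))
  # field-width bound
  co <- m$coords
  co[1, 1] <- 12345
  expect_error(write_pdb(m$topology, co, tempfile()), "overflow")
})

test_that("bio3d agrees with read_pdb on the mini fixture", {
  skip_if_not_installed("bio3d")
  m <- suppressWarnings(read_pdb(mini_pdb_path()))
  b <- bio3d::read.pdb(mini_pdb_path(), verbose = FALSE)
  ba <- b$atom[b$atom$alt %in% c(NA, "A"), ]
  expect_equal(nrow(ba), n_atoms(m$topology))
  expect_equal(unname(as.matrix(ba[, c("x", "y", "z")])),
               unname(m$coords), tolerance = 1e-6)
  expect_equal(ba$resid, m$topology$atoms$resname)
})

test_that("XYZ trajectories round-trip and reject malformed blocks", {
  top <- point_topology(1)
  f <- tempfile(fileext = ".xyz")
  writeLines(c("1", "frame 1", "CA 0.0 0.0 0.0",
               "1", "frame 2", "CA 1.0 2.0 3.0"), f)
  tr <- read_xyz_traj(f, top, frame_interval = 0.5)
  expect_equal(dim(tr$coords), c(2, 1, 3))
  expect_equal(tr$coords[2, 1, ], c(1, 2, 3))

  bad <- tempfile(fileext = ".xyz")
  writeLines(c("1", "c", "CA 0 0 0", "2", "c", "CA 0 0 0", "CA 1 1 1"), bad)
  expect_error(read_xyz_traj(bad, top, 0.5), "atom count")
  trunc <- tempfile(fileext = ".xyz")
  writeLines(c("1", "c", "CA 0 0 0", "1", "c"), trunc)
  expect_error(read_xyz_traj(trunc, top, 0.5), "frame 2")

  # generator output written then re-read: equal to 6 decimals
  gas <- gen_ideal_gas_waters(n_waters = 5, n_frames = 4, seed = 3)
  xf <- tempfile(fileext = ".xyz")
  write_xyz_traj(gas, xf)
  back <- read_xyz_traj(xf, gas$topology, gas$frame_interval)
  expect_equal(back$coords, gas$coords, tolerance = 1e-6)
})

test_that("DCD reader handles both byte orders and validates headers", {
  set.seed(11)
  top <- point_topology(7)
  coords <- array(stats::rnorm(2 * 7 * 3, sd = 10), c(2, 7, 3))
  for (e in c("little", "big")) {
    path <- tempfile(fileext = ".dcd")
    write_dcd_fixture(coords, path, endian = e)
    tr <- read_dcd(path, top, frame_interval = 1)
    expect_equal(tr$coords, coords, tolerance = 1e-4,
                 info = paste("endian:", e))
  }
  # empty file
  empty <- tempfile(fileext = ".dcd")
  file.create(empty)
  expect_error(read_dcd(empty, top, 1), "DCD")
  nomagic <- tempfile(fileext = ".dcd")
  con <- file(nomagic, "wb")
  writeBin(84L, con, size = 4)
  writeChar("XORD", con, 4, eos = NULL)
  writeBin(integer(20), con, size = 4)
  writeBin(84L, con, size = 4)
  close(con)
  expect_error(read_dcd(nomagic, top, 1), "CORD")
  # header frame count inconsistent with file size
  lying <- tempfile(fileext = ".dcd")
  write_dcd_fixture(coords, lying, nset = 5)
  expect_error(read_dcd(lying, top, 1), "inconsistent")
})

test_that("DCD reader agrees with an mdtraj-written file", {
  skip_if(!python_available("mdtraj"), "python/mdtraj not available")
  set.seed(12)
  top <- point_topology(3)
  coords <- array(stats::rnorm(2 * 3 * 3, sd = 5), c(2, 3, 3))
  pdb <- tempfile(fileext = ".pdb")
  write_pdb(top, coords[1, , ], pdb)
  dcd <- tempfile(fileext = ".dcd")
  mdtraj_write_dcd(pdb, coords, dcd)
  tr <- read_dcd(dcd, top, frame_interval = 1)
  expect_equal(tr$coords, coords, tolerance = 1e-4)
})

test_that("write_dx emits z-fastest OpenDX that an independent reader reproduces", {
  vals <- array(0, c(2, 2, 2))
  g0 <- occupancy_grid_obj(c(0, 0, 0), 1, vals, frames_used = 1)
  p0 <- tempfile(fileext = ".dx")
  write_dx(g0, p0)
  txt <- readLines(p0)
  datstart <- grep("data follows", txt) + 1
  dat <- as.numeric(unlist(strsplit(txt[datstart:(datstart + 2)], " ")))
  expect_equal(dat, rep(0, 8))

  # single 1.0 voxel at [2,1,1]: z-fastest order puts it 5th
  vals[2, 1, 1] <- 1
  g1 <- occupancy_grid_obj(c(1, 2, 3), 0.5, vals, frames_used = 10)
  p1 <- tempfile(fileext = ".dx")
  write_dx(g1, p1)
  txt <- readLines(p1)
  datstart <- grep("data follows", txt) + 1
  dat <- as.numeric(unlist(strsplit(txt[datstart:(datstart + 2)], " ")))
  expect_equal(which(dat == 1), 5)

  skip_if(!python_available("gridData"), "python/gridData not available")
  set.seed(4)
  vals <- array(runif(3 * 4 * 5), c(3, 4, 5))
  g <- occupancy_grid_obj(c(-2, 0, 7.5), 1.25, round(vals, 4), frames_used = 3)
  p <- tempfile(fileext = ".dx")
  write_dx(g, p)
  ext <- griddata_read_dx(p)
  expect_equal(ext$origin, g$origin)
  expect_equal(ext$delta, rep(1.25, 3))
  expect_equal(ext$shape, c(3L, 4L, 5L))
  expect_equal(array(ext$values, dim = c(5, 4, 3)),
               aperm(g$values, c(3, 2, 1)), tolerance = 1e-9)
})

test_that("write_table emits locale-safe TSV with 6 significant digits", {
  p <- tempfile(fileext = ".tsv")
  write_table(list(list("A:51:TYR", 0.123456789)),
              c("residue", "fraction"), p)
  lines <- readLines(p)
  expect_equal(lines[1], "residue\tfraction")
  expect_equal(strsplit(lines[2], "\t")[[1]][2], "0.123457")
  # header-only when no rows
  write_table(list(), c("a", "b"), p)
  expect_equal(readLines(p), "a\tb")
  expect_error(write_table(list(c(1, 2, 3)), c("a", "b"), p), "ragged")
})

test_that("selection language and masks behave consistently", {
  m <- suppressWarnings(read_pdb(mini_pdb_path()))
  top <- m$topology
  expect_equal(select_atoms(top, "water and name O")$indices, c(6L, 9L))
  expect_equal(length(select_atoms(top, "resname ALA and heavy")$indices), 5)
  expect_equal(select_atoms(top, "resid 101..102 and name O")$indices, c(6L, 9L))
  expect_error(select_atoms(top, "resname XYZ"), "matches no atoms")
  expect_error(select_atoms(top, "flavor nice"), "unknown")
  # masks partition: water/backbone disjoint, heavy contains backbone
  expect_length(intersect(which(mask_water(top)), which(mask_backbone(top))), 0)
  expect_true(all(which(mask_backbone(top)) %in% which(mask_heavy(top))))
  # unit parsing
  expect_equal(parse_length("1nm"), 10)
  expect_equal(parse_length("3.5A"), 3.5)
  expect_equal(parse_length(2.5), 2.5)
  expect_error(parse_length("ten"), "cannot parse")
})
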