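test_that("orthogonalization follows the standard convention and inverts", {
  # identity cell
  cl <- unit_cell(1, 1, 1)
  expect_equal(frac_to_cart(cl, c(0.5, 0.5, 0.5)), c(0.5, 0.5, 0.5))
  # orthorhombic scaling
  cl2 <- unit_cell(10, 20, 30)
  expect_equal(frac_to_cart(cl2, c(0.1, 0.1, 0.1)), c(1, 2, 3))
  # monoclinic: c axis tips into negative x, length preserved
  clm <- unit_cell(10, 10, 10, 90, 105, 90)
  v <- frac_to_cart(clm, c(0, 0, 1))
  expect_lt(v[1], 0)
  expect_equal(v[1], 10 * cos(105 * pi / 180), tolerance = 1e-12)
  expect_equal(sqrt(sum(v^2)), 10, tolerance = 1e-10)
  # round trip is the identity
  for (cl3 in list(cl2, clm, unit_cell(25, 20, 18, 85, 95, 102))) {
    pts <- matrix(runif(30), ncol = 3)
    expect_equal(cart_to_frac(cl3, frac_to_cart(cl3, pts)), pts,
                 tolerance = 1e-10)
  }
  expect_error(unit_cell(-1, 1, 1), "positive")
  expect_error(unit_cell(1, 1, 1, 0, 90, 90), "angles")
})

test_that("space group operators form closed sets", {
  for (sym in c("P1", "P2", "P21", "C2")) {
    sg <- spacegroup(sym)
    expect_true(mdmx:::sg_is_closed(sg))
    expect_equal(sg$ops[[1]]$R, diag(3))
  }
  expect_equal(n_ops(spacegroup("C2")), 4)
  expect_error(spacegroup("P6122"), "unsupported")
})

test_that("PDB write -> read round trip preserves the model", {
  s <- toy_pair_default$state_30s
  path <- withr::local_tempfile(fileext = ".pdb")
  write_structure(s, path)
  s2 <- read_structure(path)
  expect_equal(nrow(s2$atoms), nrow(s$atoms))
  expect_equal(s2$atoms$occ, s$atoms$occ, tolerance = 1e-2)
  # coordinates to 1e-3 Angstrom, U tensors to 1e-4 Angstrom^2 (absolute)
  dcart <- abs(atoms_cart(s2) - atoms_cart(s))
  expect_lt(max(dcart), 1e-3)
  du <- abs(as.matrix(s2$atoms[, c("u11", "u22", "u33", "u12", "u13", "u23")]) -
              as.matrix(s$atoms[, c("u11", "u22", "u33", "u12", "u13", "u23")]))
  expect_lt(max(du), 1e-4)
  expect_equal(s2$atoms$altloc, s$atoms$altloc)
  expect_equal(s2$spacegroup$symbol, "P1")
})

test_that("altloc groups are inferred from shared label and occupancy", {
  s <- toy_pair_default$state_0s
  g <- s$altgroups
  loop_a <- g[g$altloc == "A" & g$resid_min == 5, ]
  expect_equal(nrow(loop_a), 1)
  expect_equal(loop_a$resid_max, 7)
  expect_equal(loop_a$occ, 0.64)
  loop_b <- g[g$altloc == "B" & g$resid_min == 5, ]
  expect_equal(loop_b$occ, 0.36)
})

test_that("structure invariants are enforced", {
  s <- toy_pair_default$state_0s
  a <- s$atoms
  a$occ[1] <- 1.5
  expect_error(xtal_structure(s$cell, s$spacegroup, a), "occupancies")
  a <- s$atoms
  a$occ[a$altloc == "A" & a$resid == 5] <- 0.9  # A+B > 1 for those sites
  expect_error(xtal_structure(s$cell, s$spacegroup, a), "sum to > 1")
  # B derived from U: trace relation
  expect_equal(biso(s), 8 * pi^2 * (s$atoms$u11 + s$atoms$u22 + s$atoms$u33) / 3)
})

test_that("symmetry expansion replicates, wraps and conserves scattering", {
  s <- toy_pair_c2$state_0s
  p1 <- expand_to_unit_cell(s)
  expect_equal(nrow(p1$atoms), 4 * nrow(s$atoms))
  expect_equal(p1$spacegroup$symbol, "P1")
  xyz <- as.matrix(p1$atoms[, c("fx", "fy", "fz")])
  expect_true(all(xyz >= 0 & xyz < 1))
  expect_equal(total_scattering(p1), 4 * total_scattering(s))
  # idempotent on P1 output
  p1b <- expand_to_unit_cell(p1)
  expect_equal(nrow(p1b$atoms), nrow(p1$atoms))
  expect_equal(p1b$atoms$fx, p1$atoms$fx)
})

test_that("malformed and inconsistent PDB records raise named errors", {
  path <- withr::local_tempfile(fileext = ".pdb")
  writeLines(c(
    "CRYST1   25.000   20.000   18.000  90.00  90.00  90.00 P 1",
    "ATOM      1  CA  GLY A   1      bad.000   5.000   5.000  1.00 20.00           C"
  ), path)
  expect_error(read_structure(path), "line")
  writeLines(c(
    "CRYST1   25.000   20.000   18.000  90.00  90.00  90.00 P 1",
    "ATOM      1  CA  GLY A   1       5.000   5.000   5.000  1.00 20.00           C",
    "ANISOU   99  CA  GLY A   1     2000   2000   2000      0      0      0       C"
  ), path)
  expect_error(read_structure(path), "ANISOU")
  expect_error(read_structure("/nonexistent.pdb"), "not found")
})

test_that("the mmCIF subset reader recovers atoms, cell and tensors", {
  path <- withr::local_tempfile(fileext = ".cif")
  writeLines(c(
    "data_toy",
    "_cell.length_a 25.0", "_cell.length_b 20.0", "_cell.length_c 18.0",
    "_cell.angle_alpha 90.0", "_cell.angle_beta 90.0", "_cell.angle_gamma 90.0",
    "_symmetry.space_group_name_H-M 'P 1'",
    "loop_", "_atom_site.group_PDB", "_atom_site.id",
    "_atom_site.type_symbol", "_atom_site.label_atom_id",
    "_atom_site.label_alt_id", "_atom_site.auth_comp_id",
    "_atom_site.auth_asym_id", "_atom_site.auth_seq_id",
    "_atom_site.Cartn_x", "_atom_site.Cartn_y", "_atom_site.Cartn_z",
    "_atom_site.occupancy", "_atom_site.B_iso_or_equiv",
    "ATOM 1 C CA A GLY A 1 5.0 5.0 5.0 0.64 20.0",
    "ATOM 2 C CA B GLY A 1 5.5 5.6 5.0 0.36 21.0",
    "loop_", "_atom_site_anisotrop.id",
    "_atom_site_anisotrop.U[1][1]", "_atom_site_anisotrop.U[2][2]",
    "_atom_site_anisotrop.U[3][3]", "_atom_site_anisotrop.U[1][2]",
    "_atom_site_anisotrop.U[1][3]", "_atom_site_anisotrop.U[2][3]",
    "1 0.030 0.020 0.025 0.001 0.000 0.002"
  ), path)
  s <- read_structure(path)
  expect_equal(nrow(s$atoms), 2)
  expect_equal(s$atoms$occ, c(0.64, 0.36))
  expect_equal(s$atoms$fx[1], 0.2)
  expect_true(s$atoms$aniso[1])
  expect_equal(s$atoms$u11[1], 0.030)
  expect_false(s$atoms$aniso[2])
})

test_that("reflection TSV and CCP4 map files round-trip", {
  s <- toy_small$state_0s
  r <- sf_direct(s, dmin = 2.5)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_reflections(r, path)
  r2 <- read_reflections(path, s$cell)
  expect_equal(Mod(r2$tbl$F), Mod(r$tbl$F), tolerance = 1e-5)
  expect_equal(Arg(r2$tbl$F), Arg(r$tbl$F), tolerance = 1e-3)

  g <- sample_density(s, c(18, 16, 15))
  mpath <- withr::local_tempfile(fileext = ".map")
  write_ccp4(g, mpath)
  g2 <- read_ccp4(mpath)
  expect_equal(g2$dim, g$dim)
  expect_equal(g2$values, g$values, tolerance = 1e-6)
  expect_equal(g2$cell$a, 21)
})

test_that("the mmCIF structure-factor block reader parses amplitudes", {
  path <- withr::local_tempfile(fileext = ".cif")
  writeLines(c(
    "data_sf", "loop_",
    "_refln.index_h", "_refln.index_k", "_refln.index_l",
    "_refln.F_meas_au", "_refln.F_meas_sigma_au",
    "1 0 0 12.5 0.3", "0 1 0 8.1 0.2", "0 0 1 5.0 0.1"
  ), path)
  r <- read_mmcif_sf(path, unit_cell(10, 10, 10))
  expect_equal(nrow(r$tbl), 3)
  expect_equal(r$tbl$fobs, c(12.5, 8.1, 5.0))
})
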