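test_that("direct summation matches closed forms for elementary models", {
  cl <- unit_cell(10, 10, 10)
  one_c <- function(fx, fy, fz, occ = 1, b = 0) {
    xtal_structure(cl, spacegroup("P1"), tibble::tibble(
      record = "ATOM", chain = "A", resid = 1L, resname = "GLY", name = "C",
      altloc = "", element = "C", fx = fx, fy = fy, fz = fz, occ = occ,
      u_from_biso(b), aniso = FALSE
    ))
  }
  hkl <- rbind(c(1, 0, 0), c(2, 1, 0), c(3, 2, 1))
  # one C at origin, occ 1, B 0: F(h) = f_C(s), phase 0
  r <- sf_direct(one_c(0, 0, 0), hkl = hkl)
  s <- d_spacing(cl, hkl)
  fC <- form_factor("C", 1 / s)[, 1]
  expect_equal(Re(r$tbl$F), fC, tolerance = 1e-12)
  expect_equal(Im(r$tbl$F), rep(0, 3), tolerance = 1e-12)
  # halving occupancy halves every |F|
  r2 <- sf_direct(one_c(0.3, 0.2, 0.1, occ = 0.5), hkl = hkl)
  r1 <- sf_direct(one_c(0.3, 0.2, 0.1, occ = 1.0), hkl = hkl)
  expect_equal(Mod(r2$tbl$F), Mod(r1$tbl$F) / 2, tolerance = 1e-12)
  # centrosymmetric pair gives real F
  s2 <- one_c(0.1, 0.05, 0.2)
  a2 <- dplyr::bind_rows(s2$atoms, s2$atoms)
  a2$fx[2] <- -0.1 %% 1; a2$fy[2] <- -0.05 %% 1; a2$fz[2] <- -0.2 %% 1
  a2$resid <- c(1L, 2L)
  pair <- xtal_structure(cl, spacegroup("P1"), a2)
  rp <- sf_direct(pair, hkl = hkl)
  expect_lt(max(abs(Im(rp$tbl$F))), 1e-10)
  # form factors at s = 0 count electrons
  expect_equal(as.numeric(form_factor(c("C", "N", "O", "S", "MG", "CL", "K", "H"), 0)),
               c(6, 7, 8, 16, 12, 17, 19, 1), tolerance = 0.1)
  expect_error(sf_direct(one_c(0, 0, 0)), "hkl or dmin")
})

test_that("Friedel symmetry holds for real scatterers", {
  s <- toy_small$state_30s
  hkl <- miller_indices(s$cell, 2.5)
  r_pos <- sf_direct(s, hkl = hkl)
  r_neg <- sf_direct(s, hkl = -hkl)
  expect_lt(max(Mod(r_pos$tbl$F - Conj(r_neg$tbl$F))) / max(Mod(r_pos$tbl$F)),
            1e-10)
})

test_that("FFT path agrees with direct summation on all fixtures", {
  fixtures <- list(
    p1_0s = list(s = toy_pair_default$state_0s, dmin = 1.5),
    p1_30s = list(s = toy_pair_default$state_30s, dmin = 1.5),
    c2 = list(s = toy_pair_c2$state_0s, dmin = 2.0),
    small = list(s = toy_small$state_0s, dmin = 1.8)
  )
  for (nm in names(fixtures)) {
    fx <- fixtures[[nm]]
    rd <- sf_direct(fx$s, dmin = fx$dmin)
    rf <- sf_fft(fx$s, dmin = fx$dmin)
    expect_lt(r_factor(rd, rf), 0.01, label = paste("R for", nm))
  }
})

test_that("grid refinement converges the FFT amplitudes", {
  s <- toy_small$state_0s
  r1 <- sf_fft(s, dmin = 2.0, grid_rule = 1 / 3)
  r2 <- sf_fft(s, dmin = 2.0, grid_rule = 1 / 6)
  expect_lt(r_factor(r2, r1), 0.002)
  expect_error(sf_fft(s, dmin = 2.0, grid_rule = 0.8), "Nyquist")
})

test_that("C2 symmetry summation equals the P1-expanded path", {
  s <- toy_pair_c2$state_0s
  r_sym <- sf_direct(s, dmin = 2.5)
  r_p1 <- sf_direct(expand_to_unit_cell(s), hkl = as.matrix(r_sym$tbl[, 1:3]))
  expect_lt(max(Mod(r_sym$tbl$F - r_p1$tbl$F)) / max(Mod(r_sym$tbl$F)), 1e-6)
  rf_sym <- sf_fft(s, dmin = 2.5)
  rf_p1 <- sf_fft(expand_to_unit_cell(s), dmin = 2.5)
  m <- dplyr::inner_join(rf_sym$tbl, rf_p1$tbl, by = c("h", "k", "l"))
  expect_lt(max(Mod(m$F.x - m$F.y)) / max(Mod(m$F.x)), 1e-6)
})

test_that("map synthesis inverts analysis and localizes atoms", {
  s <- toy_small$state_0s
  r <- sf_fft(s, dmin = 1.8)
  shape <- grid_dim_for(s$cell, 1.8)
  g <- map_from_sf(r, shape)
  # synthesis then analysis returns the input F
  Farr <- stats::fft(g$values, inverse = TRUE) * s$cell$volume / prod(shape)
  hkl <- as.matrix(r$tbl[, 1:3])
  idx <- cbind(hkl[, 1] %% shape[1], hkl[, 2] %% shape[2],
               hkl[, 3] %% shape[3]) + 1
  expect_lt(max(Mod(Farr[idx] - r$tbl$F)) / max(Mod(r$tbl$F)), 1e-8)
  # Parseval: grid power equals reciprocal power (Friedel pairs doubled)
  lhs <- sum(g$values^2) * s$cell$volume / prod(shape)
  rhs <- 2 * sum(Mod(r$tbl$F)^2) / s$cell$volume
  expect_equal(lhs, rhs, tolerance = 1e-6)
  # map peaks sit on atoms: every strong maximum is near some atom
  pks <- find_peaks(g, threshold_sigma = 3, model = s, max_dist = 1.0)
  expect_gt(nrow(pks), 0)
  expect_lt(stats::median(pks$dist[seq_len(min(10, nrow(pks)))]), 0.5)
  # all F = 0 gives the zero map
  r0 <- reflection_set(s$cell, tibble::tibble(h = 1L, k = 0L, l = 0L,
                                              F = 0 + 0i), dmin = 3)
  g0 <- map_from_sf(r0, c(8, 8, 8))
  expect_equal(max(abs(g0$values)), 0)
  # amplitudes without phases are refused
  obs <- make_observations(s, 3, 0, 1)
  expect_error(map_from_sf(obs), "phases")
})

test_that("ensemble averaging degenerates, respects periodicity, and matches occupancies", {
  s <- toy_small$state_0s
  # degenerate ensemble equals the direct SF of its model
  ens <- make_ensemble(s, dims = c(1, 1, 1), n_frames = 1, thermal = FALSE,
                       seed = 2)
  fe <- sf_ensemble(ens, "all", dmin = 2.2)
  fd <- sf_direct(weighted_occupancy_model(s, ens$model),
                  hkl = as.matrix(fe$tbl[, 1:3]))
  expect_lt(max(Mod(fe$tbl$F - fd$tbl$F)) / max(Mod(fd$tbl$F)), 1e-10)
  # translating every frame by one supercell lattice vector changes nothing
  ens_t <- ens
  ens_t$frames <- lapply(ens_t$frames, function(fr) fr + 1)
  fe_t <- sf_ensemble(ens_t, "all", dmin = 2.2)
  expect_lt(max(Mod(fe$tbl$F - fe_t$tbl$F)) / max(Mod(fe$tbl$F)), 1e-10)
  # quota-built 32-copy ensemble of a two-conformer model (loop only;
  # 20/12 copies divide evenly over the 4 operator strata) reproduces the
  # occupancy-weighted model
  s2 <- make_toy_pair(toy_crystal_spec(
    cell = unit_cell(30, 24, 22, 90, 105, 90), spacegroup = "C2",
    occ_reactive = 1, occ_adduct = 0, occ_water = 0
  ))$state_0s
  ens2 <- make_ensemble(s2, dims = c(2, 2, 2), n_frames = 1, thermal = FALSE,
                        seed = 5)
  fe2 <- sf_ensemble(ens2, "all", dmin = 2.5)
  fw2 <- sf_direct(weighted_occupancy_model(s2, ens2$model),
                   hkl = as.matrix(fe2$tbl[, 1:3]))
  expect_lt(max(Mod(fe2$tbl$F - fw2$tbl$F)) / max(Mod(fw2$tbl$F)), 1e-6)
})

test_that("component selections are exactly additive", {
  ens <- make_ensemble(toy_pair_default$state_30s, dims = c(2, 2, 2),
                       n_frames = 2, seed = 5)
  fa <- sf_ensemble(ens, "all", dmin = 2.2)
  fp <- sf_ensemble(ens, "protein", dmin = 2.2)
  fw <- sf_ensemble(ens, "water", dmin = 2.2)
  fad <- sf_ensemble(ens, "adduct", dmin = 2.2)
  expect_lt(max(Mod(fa$tbl$F - fp$tbl$F - fw$tbl$F - fad$tbl$F)) /
              max(Mod(fa$tbl$F)), 1e-12)
  expect_error(sf_ensemble(ens, "MG", dmin = 2.2), "empty selection")
})
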