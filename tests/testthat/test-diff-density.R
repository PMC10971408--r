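# shared noise-free observation sets for the map tests
obs0_nf <- make_observations(toy_pair_default$state_0s, dmin = 1.8,
                             noise_frac = 0, seed = 1)
obs30_nf <- make_observations(toy_pair_default$state_30s, dmin = 1.8,
                              noise_frac = 0, seed = 2)

test_that("amplitude scaling recovers exact and noisy scale factors", {
  # exact scalar
  doubled <- reflection_set(obs0_nf$cell, tibble::tibble(
    h = obs0_nf$tbl$h, k = obs0_nf$tbl$k, l = obs0_nf$tbl$l,
    fobs = 2 * obs0_nf$tbl$fobs, sigf = 0
  ), obs0_nf$dmin)
  sc <- scale_amplitudes(obs0_nf, doubled)
  expect_equal(sc$k, 0.5, tolerance = 1e-12)
  expect_equal(sc$scaled$tbl$fobs, sc$ref$tbl$fobs, tolerance = 1e-12)
  # identity
  expect_equal(scale_amplitudes(obs0_nf, obs0_nf)$k, 1, tolerance = 1e-12)
  # Monte-Carlo recovery at known k under multiplicative noise
  k_true <- 1.7
  khat <- vapply(1:60, function(i) {
    noisy <- make_observations(toy_small$state_0s, dmin = 2.5,
                               noise_frac = 0.05, seed = 100 + i)
    ref <- make_observations(toy_small$state_0s, dmin = 2.5,
                             noise_frac = 0, seed = 1)
    ref$tbl$fobs <- k_true * ref$tbl$fobs
    scale_amplitudes(ref, noisy)$k
  }, numeric(1))
  se <- stats::sd(khat) / sqrt(length(khat))
  expect_lt(abs(mean(khat) - k_true), 3 * se + 1e-4)
  # too few common reflections
  tiny <- reflection_set(obs0_nf$cell, obs0_nf$tbl[1:10, ], obs0_nf$dmin)
  expect_error(scale_amplitudes(tiny, tiny), "common reflections")
})

test_that("identical inputs give a machine-zero map and empty peak list", {
  m0 <- fo_minus_fo_map(obs0_nf, obs0_nf, toy_pair_default$state_0s,
                        dmin = 1.8)
  expect_lt(max(abs(m0$values)), 1e-10)
  expect_equal(nrow(find_peaks(m0, 3, toy_pair_default$state_0s)), 0)
  prof <- iaddat(m0, toy_pair_default$state_0s)
  expect_true(all(prof$value == 0))
})

test_that("a constructed half-occupancy oxygen is recovered as the top peak", {
  s0 <- toy_pair_default$state_0s
  a <- s0$atoms
  extra <- a[1, ]
  extra$record <- "HETATM"; extra$name <- "O"; extra$element <- "O"
  extra$resid <- 99L; extra$resname <- "HOH"; extra$altloc <- ""
  extra$fx <- 0.52; extra$fy <- 0.47; extra$fz <- 0.5; extra$occ <- 0.5
  s_on <- xtal_structure(s0$cell, s0$spacegroup, dplyr::bind_rows(a, extra))
  obs_on <- make_observations(s_on, dmin = 1.8, noise_frac = 0, seed = 3)
  dm <- fo_minus_fo_map(obs_on, obs0_nf, s0, dmin = 1.8)
  pk <- find_peaks(dm, 3, s_on, max_dist = 5)
  expect_gt(nrow(pk), 0)
  expect_equal(pk$sign[1], "+")
  # strongest peak within one grid spacing of the added atom
  spacing <- max(s0$cell$a / dm$dim[1], s0$cell$b / dm$dim[2],
                 s0$cell$c / dm$dim[3])
  target <- frac_to_cart(s0$cell, c(0.52, 0.47, 0.5))
  expect_lt(sqrt(sum((c(pk$x[1], pk$y[1], pk$z[1]) - target)^2)), spacing)
})

test_that("difference maps are antisymmetric under order exchange", {
  # exact on pre-scaled sets
  d1 <- fo_minus_fo_map(obs30_nf, obs0_nf, toy_pair_default$state_0s,
                        dmin = 1.8, scale = "none")
  d2 <- fo_minus_fo_map(obs0_nf, obs30_nf, toy_pair_default$state_0s,
                        dmin = 1.8, scale = "none")
  expect_lt(max(abs(d1$values + d2$values)) / max(abs(d1$values)), 1e-10)
  # near-exact once least-squares scaling intervenes
  d1s <- fo_minus_fo_map(obs30_nf, obs0_nf, toy_pair_default$state_0s,
                         dmin = 1.8)
  d2s <- fo_minus_fo_map(obs0_nf, obs30_nf, toy_pair_default$state_0s,
                         dmin = 1.8)
  expect_lt(max(abs(d1s$values + d2s$values)) / max(abs(d1s$values)), 0.15)
})

test_that("peak census is sigma-relative and monotone in the threshold", {
  dm <- fo_minus_fo_map(obs30_nf, obs0_nf, toy_pair_default$state_0s,
                        dmin = 1.8)
  n3 <- nrow(find_peaks(dm, 3.0, toy_pair_default$state_0s))
  n4 <- nrow(find_peaks(dm, 4.0, toy_pair_default$state_0s))
  n6 <- nrow(find_peaks(dm, 6.0, toy_pair_default$state_0s))
  expect_true(n3 >= n4 && n4 >= n6)
  # global scaling leaves the sigma-relative census unchanged
  dm_scaled <- density_grid(dm$cell, dm$values * 7.3)
  expect_equal(nrow(find_peaks(dm_scaled, 3.0, toy_pair_default$state_0s)), n3)
  # peaks carry both signs and are sorted by |height|
  pk <- find_peaks(dm, 3.0, toy_pair_default$state_0s)
  expect_setequal(unique(pk$sign), c("+", "-"))
  expect_true(all(diff(abs(pk$height)) <= 1e-12))
  expect_true(all(abs(pk$height_sigma) >= 3.0))
})

test_that("the gated-water signature appears only when the water is present", {
  s30 <- toy_pair_default$state_30s
  wat <- s30$atoms[s30$atoms$resname == "HOH", ]
  wat_frac <- c(wat$fx, wat$fy, wat$fz)
  dm <- fo_minus_fo_map(obs30_nf, obs0_nf, toy_pair_default$state_0s,
                        dmin = 1.8)
  pk <- find_peaks(dm, 3.0, s30, max_dist = 5)
  d_wat <- mdmx:::min_image_dist(dm$cell,
                                 as.matrix(pk[, c("fx", "fy", "fz")]), wat_frac)
  expect_true(any(d_wat < 3 & pk$sign == "+"))
  # the strongest positive peak near the water site is the map's top peak
  expect_lt(d_wat[1], 3)
  expect_equal(pk$sign[1], "+")

  # negative control: same experiment with the water switched off
  pair_dry <- make_toy_pair(toy_crystal_spec(occ_water = 0))
  obs_dry <- make_observations(pair_dry$state_30s, dmin = 1.8,
                               noise_frac = 0, seed = 4)
  dm_dry <- fo_minus_fo_map(obs_dry, obs0_nf, pair_dry$state_0s, dmin = 1.8)
  pk_dry <- find_peaks(dm_dry, 3.0, pair_dry$state_30s, max_dist = 5)
  if (nrow(pk_dry)) {
    d_dry <- mdmx:::min_image_dist(dm_dry$cell,
                                   as.matrix(pk_dry[, c("fx", "fy", "fz")]),
                                   wat_frac)
    expect_false(any(d_dry < 1.5 & pk_dry$sign == "+" &
                       abs(pk_dry$height_sigma) >
                         0.5 * abs(pk_dry$height_sigma[1])))
  }
})

test_that("IADDAT is non-negative, localized and zero below threshold", {
  dm <- fo_minus_fo_map(obs30_nf, obs0_nf, toy_pair_default$state_0s,
                        dmin = 1.8)
  prof <- iaddat(dm, toy_pair_default$state_0s)
  expect_true(all(prof$value >= 0))
  expect_equal(nrow(prof), 10)
  # signal concentrates at the active site / loop residues (3..7)
  expect_true(which.max(prof$value) %in% 3:7)
  hot <- mean(prof$value[prof$resid %in% 3:7])
  cold <- mean(prof$value[prof$resid %in% c(1, 9, 10)])
  expect_gt(hot, 2 * cold)
  # uniform sub-threshold map gives all zeros
  flat <- density_grid(dm$cell, array(0.01, dm$dim), sigma = 1)
  expect_true(all(iaddat(flat, toy_pair_default$state_0s)$value == 0))
})

test_that("masked map correlation behaves as a correlation", {
  dm <- fo_minus_fo_map(obs30_nf, obs0_nf, toy_pair_default$state_0s,
                        dmin = 1.8)
  expect_equal(map_cc_masked(dm, dm, toy_pair_default$state_0s), 1)
  neg <- density_grid(dm$cell, -dm$values)
  expect_equal(map_cc_masked(dm, neg, toy_pair_default$state_0s), -1)
  # maps from independent random phase sets decorrelate
  s <- toy_pair_default$state_0s
  hkl <- miller_indices(s$cell, 2.5)
  shape <- grid_dim_for(s$cell, 2.5)
  rand_map <- function(seed) {
    set.seed(seed)
    amp <- stats::runif(nrow(hkl), 0, 1)
    phi <- stats::runif(nrow(hkl), -pi, pi)
    r <- reflection_set(s$cell, tibble::tibble(
      h = hkl[, 1], k = hkl[, 2], l = hkl[, 3],
      F = complex(modulus = amp, argument = phi)
    ), 2.5)
    map_from_sf(r, shape)
  }
  ccs <- vapply(1:60, function(i) {
    map_cc_masked(rand_map(2 * i), rand_map(2 * i + 1), s, radius = 2.5)
  }, numeric(1))
  expect_lt(abs(mean(ccs)), 0.1)
  # undersized masks are refused
  one_atom <- filter_atoms(s, .data$resid == 1, .data$name == "N")
  expect_error(map_cc_masked(dm, dm, one_atom, selection = "all",
                             radius = 0.2), "10 grid points")
})
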