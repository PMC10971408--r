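test_that("quota assignment reproduces refined occupancies at small copy counts", {
  s <- toy_pair_c2$state_0s  # 4 ops x 8 cells = 32 copies
  model <- assign_conformers(s, c(2, 2, 2), seed = 3, absent_ok = TRUE)
  expect_equal(nrow(model$copies), 32)
  freq <- conformer_frequencies(model)
  loop <- freq[freq$site == "A:5-7", ]
  # round(32 * 0.64) = 20 closed / 12 open via largest remainder
  expect_equal(loop$n[loop$altloc == "A"], 20)
  expect_equal(loop$n[loop$altloc == "B"], 12)
  # realized frequencies deviate from occupancies by < 1/N
  sites <- conformer_sites(s)
  m <- merge(as.data.frame(freq), as.data.frame(sites),
             by = c("site", "altloc"))
  expect_true(all(abs(m$freq - m$occ) < 1 / 32))
  # even split is exact
  s5050 <- make_toy_pair(toy_crystal_spec(
    cell = unit_cell(30, 24, 22, 90, 105, 90), spacegroup = "C2",
    occ_closed = 0.5
  ))$state_0s
  m2 <- assign_conformers(s5050, c(2, 2, 2), seed = 1, absent_ok = TRUE)
  f2 <- conformer_frequencies(m2)
  expect_equal(f2$n[f2$site == "A:5-7"], c(16, 16))
})

test_that("multinomial assignment converges to the occupancies", {
  s <- toy_small$state_0s
  model <- assign_conformers(s, c(50, 50, 40), seed = 11,
                             method = "multinomial", absent_ok = TRUE)
  freq <- conformer_frequencies(model)
  closed <- freq$freq[freq$site == "A:2-3" & freq$altloc == "A"]
  expect_lt(abs(closed - 0.64), 0.005)
})

test_that("under-filled sites error unless an absent state is declared", {
  s <- toy_pair_default$state_30s  # water site sums to 0.64
  expect_error(assign_conformers(s, c(2, 2, 2), absent_ok = FALSE),
               "absent")
  expect_silent(assign_conformers(s, c(2, 2, 2), absent_ok = TRUE,
                                  exclude_sites = "A:90-90"))
})

test_that("adduct assignment is conditional on the reactive conformer", {
  s <- toy_pair_default$state_30s
  model <- assign_conformers(s, c(4, 4, 2), seed = 5, absent_ok = TRUE,
                             exclude_sites = "A:90-90")
  # p = 1: every reactive copy carries the adduct
  m1 <- assign_adduct(model, 1, host_site = "A:3-3",
                      adduct_site = "A:90-90", seed = 6)
  hosts <- m1$assignment[m1$assignment$site == "A:3-3", ]
  reactive <- hosts$copy[hosts$altloc == "A"]
  expect_setequal(which(m1$copies$adduct), reactive)
  # p = 0: no-op
  m0 <- assign_adduct(model, 0, host_site = "A:3-3",
                      adduct_site = "A:90-90", seed = 6)
  expect_false(any(m0$copies$adduct))
  # quota count = round(n_reactive * p), adducts only on reactive copies
  m.62 <- assign_adduct(model, 0.62, host_site = "A:3-3",
                        adduct_site = "A:90-90", seed = 6)
  expect_equal(sum(m.62$copies$adduct), round(length(reactive) * 0.62))
  expect_true(all(which(m.62$copies$adduct) %in% reactive))
})

test_that("the printed worked example holds: 27 reactive copies, 17 adducts", {
  # 32 copies at occupancy 0.85 -> 27 reactive; p = 0.62 -> 17 adducts
  expect_equal(round(32 * 0.85), 27)
  s <- make_toy_pair(toy_crystal_spec(occ_water = 0))$state_30s
  model <- assign_conformers(s, c(4, 4, 2), seed = 2, absent_ok = TRUE,
                             exclude_sites = "A:90-90")
  hosts <- model$assignment[model$assignment$site == "A:3-3", ]
  expect_equal(sum(hosts$altloc == "A"), 27)
  m <- assign_adduct(model, 0.62, host_site = "A:3-3",
                     adduct_site = "A:90-90", seed = 3)
  expect_equal(sum(m$copies$adduct), 17)
})

test_that("modification fraction is the occupancy ratio in percent", {
  expect_equal(round(modification_fraction(0.53, 0.85)), 62)
  expect_equal(modification_fraction(0.5, 1.0), 50)
  expect_equal(modification_fraction(0, 0.7), 0)
  expect_error(modification_fraction(0.9, 0.85), "occ_adduct")
  expect_error(modification_fraction(0.1, 0), "occ_host")
})

test_that("ion counts follow N = round(C V N_A) with configurable rounding", {
  v <- 1.0379e-21
  expect_equal(ion_counts(c(MG = 0.125), v)$count, 78L)
  expect_equal(ion_counts(c(K = 0.050), v)$count, 31L)
  expect_equal(ion_counts(c(X = 0), v)$count, 0L)
  # contributions from several buffer components sum before rounding
  both <- ion_counts(c(CL = 0.250, CL = 0.067, CL = 0.050), v)
  expect_equal(both$count, 229L)
  expect_equal(ion_counts(c(K = 0.050), v, rounding = "ceiling")$count, 32L)
  expect_error(ion_counts(c(MG = -1), v), "negative")
})

test_that("realization makes disorder explicit and conserves electrons", {
  # identity: single-conformer P1 base, dims (1,1,1)
  s <- toy_small$state_0s
  single <- filter_atoms(s, .data$altloc %in% c("", "A"))
  a <- single$atoms; a$occ <- 1; a$altloc <- ""
  single <- xtal_structure(s$cell, s$spacegroup, a)
  m <- assign_conformers(toy_small$state_0s, c(1, 1, 1), seed = 1,
                         absent_ok = TRUE)
  r1 <- realize(m)
  expect_true(all(r1$atoms$occ == 1))
  expect_equal(nrow(r1$atoms) + 0, sum(!is.na(r1$atoms$occ)))

  # C2 toy, 2x2x2: 32 copies, supercell cell, electron conservation
  s2 <- toy_pair_c2$state_0s
  m2 <- assign_conformers(s2, c(2, 2, 2), seed = 3, absent_ok = TRUE)
  r2 <- realize(m2)
  expect_equal(r2$cell$a, 2 * s2$cell$a)
  expect_equal(r2$spacegroup$symbol, "P1")
  per_copy <- nrow(filter_atoms(s2, .data$altloc %in% c("", "A"))$atoms)
  expect_equal(nrow(r2$atoms), 32 * per_copy)
  # quota at exactly representable proportions conserves total scattering
  s_even <- make_toy_pair(toy_crystal_spec(
    cell = unit_cell(30, 24, 22, 90, 105, 90), spacegroup = "C2",
    occ_closed = 0.5, occ_reactive = 0.75
  ))$state_0s
  m3 <- assign_conformers(s_even, c(2, 2, 2), seed = 4, absent_ok = TRUE)
  r3 <- realize(m3)
  expect_equal(total_scattering(r3), 32 * total_scattering(s_even),
               tolerance = 1e-12)
})

test_that("manifests record the realization deterministically", {
  s <- toy_pair_default$state_0s
  m <- assign_conformers(s, c(2, 1, 1), seed = 8, absent_ok = TRUE)
  m_again <- assign_conformers(s, c(2, 1, 1), seed = 8, absent_ok = TRUE)
  expect_identical(m$assignment, m_again$assignment)
  p1 <- withr::local_tempfile(fileext = ".json")
  p2 <- withr::local_tempfile(fileext = ".json")
  write_manifest(m, p1); write_manifest(m_again, p2)
  expect_identical(readLines(p1), readLines(p2))
})
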