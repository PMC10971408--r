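# shared fixtures, built once per test run

toy_pair_default <- make_toy_pair(toy_crystal_spec())

toy_pair_c2 <- make_toy_pair(
  toy_crystal_spec(cell = unit_cell(30, 24, 22, 90, 105, 90),
                   spacegroup = "C2")
)

# a small quick structure for expensive Monte Carlo style checks
toy_small_spec <- toy_crystal_spec(
  cell = unit_cell(21, 14, 13), n_residues = 4, loop_range = 2:3,
  nucleophile_resid = 1
)
toy_small <- make_toy_pair(toy_small_spec)

# occupancy-weighted copy of a structure with conformer occupancies
# replaced by realized supercell frequencies and all ADPs zeroed --
# the oracle for ensemble/occupancy equivalence
weighted_occupancy_model <- function(s, model) {
  freq <- conformer_frequencies(model)
  sites <- conformer_sites(s)
  a <- s$atoms
  # conformers that realized zero copies must drop to occupancy 0
  for (r in seq_len(nrow(sites))) {
    hit <- a$chain == sites$chain[r] & a$altloc == sites$altloc[r] &
      a$resid >= sites$resid_min[r] & a$resid <= sites$resid_max[r]
    a$occ[hit] <- 0
  }
  for (r in seq_len(nrow(freq))) {
    row <- sites[sites$site == freq$site[r] & sites$altloc == freq$altloc[r], ]
    if (nrow(row)) {
      hit <- a$chain == row$chain & a$altloc == row$altloc &
        a$resid >= row$resid_min & a$resid <= row$resid_max
      a$occ[hit] <- freq$freq[r]
    }
  }
  if (any(a$resname == "ADT")) {
    a$occ[a$resname == "ADT"] <- sum(model$copies$adduct) / nrow(model$copies)
  }
  a[, c("u11", "u22", "u33", "u12", "u13", "u23")] <- 0
  a$aniso <- FALSE
  xtal_structure(s$cell, s$spacegroup, a)
}

expect_close <- function(actual, expected, tol) {
  expect_true(abs(actual - expected) <= tol,
              label = sprintf("|%.6g - %.6g| <= %.3g", actual, expected, tol))
}
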