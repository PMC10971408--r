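#' Toy crystal specification
#'
#' Parameters of the synthetic two-state toy crystal used to exercise the
#' whole pipeline. Defaults mirror the statistical structure of a
#' mix-and-inject experiment on a cysteine hydrolase: a two-conformer
#' active-site loop whose closed conformer drops from 0.64 to 0.39 on
#' intermediate formation, a nucleophile side chain with a reactive (0.85)
#' and an inert (0.15) conformer, a covalent adduct at 0.53 occupancy on
#' the reactive conformer only, and a gated water (0.64) that binds within
#' steric-clash distance of the closed loop conformer.
#'
#' Residues are 4-atom main-chain (N, CA, C, O) plus one side-chain
#' pseudo-atom; the adduct is a 3-atom planar group bonded to the
#' nucleophile sulfur. The default cell (25 x 20 x 18 Angstrom, P1, 10
#' residues) keeps FFTs at seconds scale; `spacegroup = "C2"` exercises the
#' symmetry paths.
#'
#' @param cell A [unit_cell()].
#' @param spacegroup A [spacegroup()] symbol or object.
#' @param n_residues Residue count.
#' @param loop_range Residues carrying the two-conformer loop.
#' @param loop_shift Displacement of the open conformer (Angstrom).
#' @param occ_closed Closed-loop occupancy in the resting state.
#' @param occ_closed_30s Closed-loop occupancy after intermediate formation.
#' @param nucleophile_resid Residue bearing the reactive side chain.
#' @param occ_reactive Occupancy of the reactive side-chain conformer.
#' @param occ_adduct Adduct occupancy (at most `occ_reactive`).
#' @param occ_water Gated-water occupancy in the 30 s state.
#' @param adp_scale Baseline isotropic B (Angstrom^2).
#' @param adp_bump_30s Extra B (Angstrom^2) on active-site/loop residues in
#'   the 30 s state, emulating the ADP increase on intermediate formation.
#' @param seed RNG seed for deterministic generation.
#' @return A `toy_crystal_spec` list.
#' @export
toy_crystal_spec <- function(cell = unit_cell(25, 20, 18),
                             spacegroup = "P1",
                             n_residues = 10,
                             loop_range = 5:7,
                             loop_shift = 1.2,
                             occ_closed = 0.64,
                             occ_closed_30s = 0.39,
                             nucleophile_resid = 3,
                             occ_reactive = 0.85,
                             occ_adduct = 0.53,
                             occ_water = 0.64,
                             adp_scale = 15,
                             adp_bump_30s = 4,
                             seed = 1L) {
  if (is.character(spacegroup)) spacegroup <- spacegroup(spacegroup)
  occs <- c(occ_closed, occ_closed_30s, occ_reactive, occ_adduct, occ_water)
  if (any(occs < 0 | occs > 1)) stop("occupancies must lie in [0,1]", call. = FALSE)
  if (occ_adduct > occ_reactive) {
    stop("occ_adduct must not exceed occ_reactive", call. = FALSE)
  }
  if (min(loop_range) < 1 || max(loop_range) > n_residues) {
    stop("loop_range must lie within the chain", call. = FALSE)
  }
  structure(list(
    cell = cell, spacegroup = spacegroup, n_residues = n_residues,
    loop_range = loop_range, loop_shift = loop_shift,
    occ_closed = occ_closed, occ_closed_30s = occ_closed_30s,
    nucleophile_resid = nucleophile_resid, occ_reactive = occ_reactive,
    occ_adduct = occ_adduct, occ_water = occ_water,
    adp_scale = adp_scale, adp_bump_30s = adp_bump_30s, seed = seed
  ), class = "toy_crystal_spec")
}

# deterministic backbone layout: two antiparallel rows of residues with
# generous spacing, everything well inside the default cell
toy_backbone <- function(spec, resid) {
  row <- (resid - 1) %/% 5
  col <- (resid - 1) %% 5
  bx <- 2.5 + 4.4 * col
  by <- 5.0 + 8.5 * row
  bz <- 9.0 + 1.1 * cos(resid * 0.7)
  side_elem <- c("C", "N", "O")[(resid %% 3) + 1]
  tibble::tibble(
    name = c("N", "CA", "C", "O", "SC"),
    element = c("N", "C", "C", "O", side_elem),
    x = bx + c(0, 0.8, 1.6, 1.6, 0.8),
    y = by + c(0, 0.9, 0.3, -0.5, 2.2),
    z = bz + c(0, 0, 0.6, 1.3, -0.9)
  )
}

# small deterministic anisotropic U: isotropic base elongated along x
toy_adp <- function(b, elongation = 0.25) {
  u <- b / (8 * pi^2)
  tibble::tibble(u11 = u * (1 + elongation), u22 = u * (1 - elongation / 2),
                 u33 = u * (1 - elongation / 2), u12 = 0, u13 = 0, u23 = 0)
}

toy_state <- function(spec, state = c("0s", "30s")) {
  state <- match.arg(state)
  loop <- spec$loop_range
  occ_closed <- if (state == "0s") spec$occ_closed else spec$occ_closed_30s
  nuc <- spec$nucleophile_resid
  rows <- list()
  for (r in seq_len(spec$n_residues)) {
    bb <- toy_backbone(spec, r)
    if (r == nuc) {
      bb$element[bb$name == "SC"] <- "S"
      bb$name[bb$name == "SC"] <- "SG"
    }
    b_base <- spec$adp_scale * (1 + 0.12 * sin(r * 1.3))
    hot <- r %in% loop || r == nuc
    if (state == "30s" && hot) b_base <- b_base + spec$adp_bump_30s
    if (r %in% loop) {
      closed <- bb |>
        dplyr::mutate(altloc = "A", occ = occ_closed)
      open <- bb |>
        dplyr::mutate(x = .data$x + 0, y = .data$y + spec$loop_shift * 0.8,
                      z = .data$z + spec$loop_shift * 0.6,
                      altloc = "B", occ = 1 - occ_closed)
      res <- dplyr::bind_rows(closed, open)
    } else if (r == nuc) {
      main <- bb[bb$name != "SG", ] |>
        dplyr::mutate(altloc = "", occ = 1)
      sg <- bb[bb$name == "SG", ]
      reac <- sg |> dplyr::mutate(altloc = "A", occ = spec$occ_reactive)
      inert <- sg |>
        dplyr::mutate(y = .data$y - 3.4, z = .data$z + 0.9,
                      altloc = "B", occ = 1 - spec$occ_reactive)
      res <- dplyr::bind_rows(main, reac, inert)
    } else {
      res <- bb |> dplyr::mutate(altloc = "", occ = 1)
    }
    res$record <- "ATOM"
    res$chain <- "A"
    res$resid <- r
    res$resname <- if (r == nuc) "CYS" else "GLY"
    res$b <- b_base * ifelse(res$name %in% mainchain_names, 1, 1.15)
    rows[[r]] <- res
  }
  atoms <- dplyr::bind_rows(rows)

  if (state == "30s" && spec$occ_adduct > 0) {
    sg_pos <- atoms |>
      dplyr::filter(.data$resid == nuc, .data$name == "SG", .data$altloc == "A")
    adduct <- tibble::tibble(
      name = c("C1", "N1", "O1"), element = c("C", "N", "O"),
      x = sg_pos$x + c(1.7, 2.5, 2.4), y = sg_pos$y + c(0, 1.05, -1.1),
      z = sg_pos$z + c(0.2, 0.4, 0.1),
      altloc = "A", occ = spec$occ_adduct, record = "HETATM", chain = "A",
      resid = 90L, resname = "ADT", b = spec$adp_scale * 1.2
    )
    atoms <- dplyr::bind_rows(atoms, adduct)
  }
  if (state == "30s" && spec$occ_water > 0) {
    # gated water: placed within steric-clash distance (< 2.2 A) of the
    # closed conformer of the central loop residue's side chain
    anchor <- atoms |>
      dplyr::filter(.data$resid == loop[ceiling(length(loop) / 2)],
                    .data$name == "SC", .data$altloc == "A")
    wat <- tibble::tibble(
      name = "O", element = "O",
      x = anchor$x + 1.15, y = anchor$y + 1.2, z = anchor$z + 1.0,
      altloc = "A", occ = spec$occ_water, record = "HETATM", chain = "A",
      resid = 95L, resname = "HOH", b = spec$adp_scale * 1.1
    )
    atoms <- dplyr::bind_rows(atoms, wat)
  }

  frac <- cart_to_frac(spec$cell, as.matrix(atoms[, c("x", "y", "z")]))
  u <- toy_adp(atoms$b)
  out <- tibble::tibble(
    record = atoms$record, chain = atoms$chain, resid = atoms$resid,
    resname = atoms$resname, name = atoms$name, altloc = atoms$altloc,
    element = atoms$element,
    fx = frac[, 1], fy = frac[, 2], fz = frac[, 3],
    occ = atoms$occ, u, aniso = TRUE
  )
  if (any(frac < 0 | frac >= 1)) {
    stop("clash-free placement impossible: requested geometry pushes atoms ",
         "outside the unit cell", call. = FALSE)
  }
  s <- xtal_structure(spec$cell, spec$spacegroup, out)
  check_no_clashes(s)
  s
}

# generation-time clash check: distinct residues may not approach below
# 1.0 A (conformers of the same site and bonded adduct/water are exempt
# only across compatible altlocs)
check_no_clashes <- function(s, min_dist = 1.0) {
  a <- s$atoms
  cart <- atoms_cart(s)
  n <- nrow(a)
  d2 <- as.matrix(stats::dist(cart))^2
  same_res <- outer(a$resid, a$resid, "==")
  incompatible <- outer(a$altloc, a$altloc, function(x, y)
    x != "" & y != "" & x != y)
  bad <- d2 < min_dist^2 & !same_res & !incompatible
  diag(bad) <- FALSE
  if (any(bad)) {
    ij <- which(bad, arr.ind = TRUE)[1, ]
    stop(sprintf(
      "clash-free placement impossible: atoms %s%d:%s and %s%d:%s are %.2f A apart",
      a$resname[ij[1]], a$resid[ij[1]], a$name[ij[1]],
      a$resname[ij[2]], a$resid[ij[2]], a$name[ij[2]],
      sqrt(d2[ij[1], ij[2]])
    ), call. = FALSE)
  }
  invisible(TRUE)
}

#' Generate the two-state toy crystal pair
#'
#' Builds the resting (`0 s`) and intermediate (`30 s`) structures sharing
#' one topology. The 30 s state differs only by: the covalent adduct
#' present at `occ_adduct` on the reactive nucleophile conformer, loop
#' occupancies redistributed (`occ_closed -> occ_closed_30s`), modestly
#' raised ADPs around the active site, and the gated water present at
#' `occ_water`. Generation is deterministic for a fixed spec.
#'
#' @param spec A [toy_crystal_spec()].
#' @return Named list with elements `state_0s` and `state_30s`, both
#'   [xtal_structure()] objects.
#' @export
make_toy_pair <- function(spec = toy_crystal_spec()) {
  list(state_0s = toy_state(spec, "0s"), state_30s = toy_state(spec, "30s"))
}

#' Simulate noisy observed amplitudes
#'
#' Computes exact amplitudes by direct summation and adds multiplicative
#' Gaussian noise: `sd = noise_frac * |F|`, stored in the `sigf` column.
#' `F(000)` is excluded.
#'
#' @param s A [xtal_structure()].
#' @param dmin Resolution cutoff (Angstrom).
#' @param noise_frac Relative amplitude noise (>= 0).
#' @param seed RNG seed.
#' @return A [reflection_set()] with columns `fobs`, `sigf`.
#' @export
make_observations <- function(s, dmin, noise_frac = 0.02, seed = 1L) {
  stopifnot(dmin > 0, noise_frac >= 0)
  calc <- sf_direct(s, dmin = dmin)
  amp <- Mod(calc$tbl$F)
  sig <- noise_frac * amp
  set.seed(seed)
  fobs <- amp + stats::rnorm(length(amp), sd = sig)
  reflection_set(s$cell, tibble::tibble(
    h = calc$tbl$h, k = calc$tbl$k, l = calc$tbl$l, fobs = fobs, sigf = sig
  ), dmin = calc$dmin)
}

#' Titration series specification
#'
#' @param pka Apparent pKa.
#' @param ph_values Strictly increasing pH values.
#' @param noise_sd Gaussian occupancy noise (>= 0).
#' @param direction `"protonation-favors-shifted"` (occupancy high at low
#'   pH) or `"deprotonation-favors-shifted"`.
#' @param seed RNG seed.
#' @return A `titration_spec` list.
#' @export
titration_spec <- function(pka = 5.7, ph_values = seq(4, 8, by = 0.5),
                           noise_sd = 0.02,
                           direction = c("protonation-favors-shifted",
                                         "deprotonation-favors-shifted"),
                           seed = 1L) {
  direction <- match.arg(direction)
  if (noise_sd < 0) stop("noise_sd must be non-negative", call. = FALSE)
  if (any(diff(ph_values) <= 0)) {
    stop("ph_values must be strictly increasing", call. = FALSE)
  }
  structure(list(pka = pka, ph_values = ph_values, noise_sd = noise_sd,
                 direction = direction, seed = seed),
            class = "titration_spec")
}

#' Single-pKa logistic occupancy
#'
#' The Henderson-Hasselbalch relation `[shifted]/[strained] = 10^(pH-pKa)`
#' written as an occupancy: with `direction = +1`
#' (protonation-favors-shifted) `occ(pH) = 1 / (1 + 10^(pH - pKa))`, with
#' `-1` the complement.
#'
#' @param ph pH values.
#' @param pka Apparent pKa.
#' @param direction `+1` or `-1`.
#' @return Occupancies in (0, 1).
#' @export
hh_occupancy <- function(ph, pka, direction = 1) {
  1 / (1 + 10^(direction * (ph - pka)))
}

#' Generate a noisy occupancy titration series
#'
#' @param spec A [titration_spec()].
#' @return Tibble with columns `ph`, `occupancy`, `sd`, carrying attribute
#'   `kind = "occupancy"`.
#' @export
make_titration <- function(spec = titration_spec()) {
  dirsign <- if (spec$direction == "protonation-favors-shifted") 1 else -1
  occ <- hh_occupancy(spec$ph_values, spec$pka, dirsign)
  set.seed(spec$seed)
  noisy <- pmin(1, pmax(0, occ + stats::rnorm(length(occ), sd = spec$noise_sd)))
  out <- tibble::tibble(ph = spec$ph_values, occupancy = noisy,
                        sd = rep(spec$noise_sd, length(occ)))
  attr(out, "kind") <- "occupancy"
  out
}

# internal constructor shared by generator and multi-model reader
new_supercell_frames <- function(base, dims, frames, seed = NA_integer_) {
  structure(list(base = base, dims = as.integer(dims), frames = frames,
                 seed = seed), class = "supercell_frames")
}

#' @export
print.supercell_frames <- function(x, ...) {
  cat(sprintf("<supercell_frames> %d frame(s), %d atoms, dims %d x %d x %d\n",
              length(x$frames), nrow(x$base$atoms),
              x$dims[1], x$dims[2], x$dims[3]))
  invisible(x)
}

#' Generate a multi-frame supercell ensemble
#'
#' Stand-in for a crystalline trajectory: conformers are fixed per copy by
#' quota Monte Carlo assignment (delegating to [assign_conformers()] and
#' [assign_adduct()]), then each frame adds zero-mean Gaussian atomic
#' displacements with the per-atom covariance U. Frames are indexed
#' deterministically from the seed.
#'
#' @param s A [xtal_structure()] with conformer sites (e.g. a toy state).
#' @param dims Supercell dimensions.
#' @param n_frames Number of frames (>= 1).
#' @param seed RNG seed.
#' @param thermal If `FALSE`, frames carry no displacement noise.
#' @param method Assignment method, `"quota"` or `"multinomial"`.
#' @return A `supercell_frames` object (base = realized supercell with the
#'   mean coordinates; frames = fractional coordinate matrices).
#' @export
make_ensemble <- function(s, dims = c(2, 2, 2), n_frames = 10, seed = 1L,
                          thermal = TRUE, method = "quota") {
  stopifnot(n_frames >= 1, all(dims >= 1))
  sites <- conformer_sites(s)
  adduct_rows <- s$atoms$resname == "ADT"
  adduct_site <- NULL
  host_site <- NULL
  if (any(adduct_rows)) {
    ad_res <- unique(s$atoms$resid[adduct_rows])
    ad_ch <- unique(s$atoms$chain[adduct_rows])
    adduct_site <- sprintf("%s:%d-%d", ad_ch, min(ad_res), max(ad_res))
    nuc <- unique(s$atoms$resid[s$atoms$name == "SG"])
    cand <- dplyr::filter(sites, .data$resid_min <= nuc[1],
                          .data$resid_max >= nuc[1])
    host_site <- cand$site[1]
  }
  model <- assign_conformers(s, dims, seed = seed, method = method,
                             exclude_sites = adduct_site %||% character(),
                             absent_ok = TRUE)
  if (!is.null(adduct_site)) {
    occ_ad <- s$atoms$occ[adduct_rows][1]
    occ_host <- dplyr::filter(sites, .data$site == host_site,
                              .data$altloc == "A")$occ[1]
    model <- assign_adduct(model, occ_ad / occ_host, host_site = host_site,
                           adduct_site = adduct_site, seed = seed + 1L,
                           method = method)
  }
  real <- realize(model)
  base_frac <- as.matrix(real$atoms[, c("fx", "fy", "fz")])
  frames <- vector("list", n_frames)
  set.seed(seed + 2L)
  n <- nrow(real$atoms)
  chols <- NULL
  if (thermal) {
    u6 <- as.matrix(real$atoms[, c("u11", "u22", "u33", "u12", "u13", "u23")])
    chols <- lapply(seq_len(n), function(i) {
      U <- matrix(c(u6[i, 1], u6[i, 4], u6[i, 5],
                    u6[i, 4], u6[i, 2], u6[i, 6],
                    u6[i, 5], u6[i, 6], u6[i, 3]), 3, 3)
      chol(U + diag(3) * 1e-12)
    })
  }
  for (f in seq_len(n_frames)) {
    if (thermal) {
      z <- matrix(stats::rnorm(3 * n), n, 3)
      disp <- t(vapply(seq_len(n), function(i) drop(z[i, ] %*% chols[[i]]),
                       numeric(3)))
      frames[[f]] <- base_frac + disp %*% t(real$cell$frac)
    } else {
      frames[[f]] <- base_frac
    }
  }
  out <- new_supercell_frames(real, dims, frames, seed = seed)
  out$model <- model
  out
}
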