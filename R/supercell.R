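#' Conformer sites of a multi-conformer structure
#'
#' Occupancy groups ([infer_altgroups()]) sharing one chain/residue range
#' form a *site*: a set of mutually exclusive conformers whose occupancies
#' describe the fraction of unit cells populating each. Sites are the unit
#' of Monte Carlo conformer assignment in supercell construction.
#'
#' @param s A [xtal_structure()].
#' @return Tibble with columns `site`, `chain`, `resid_min`, `resid_max`,
#'   `altloc`, `occ` (one row per conformer).
#' @export
conformer_sites <- function(s) {
  g <- s$altgroups
  if (!nrow(g)) {
    return(tibble::tibble(site = character(), chain = character(),
                          resid_min = integer(), resid_max = integer(),
                          altloc = character(), occ = double()))
  }
  g |>
    dplyr::mutate(site = sprintf("%s:%d-%d", .data$chain, .data$resid_min,
                                 .data$resid_max)) |>
    dplyr::select("site", "chain", "resid_min", "resid_max", "altloc", "occ") |>
    dplyr::arrange(.data$site, .data$altloc)
}

# largest-remainder apportionment of n among proportions p (sums to n)
largest_remainder <- function(p, n) {
  raw <- p * n
  base <- floor(raw)
  short <- n - sum(base)
  if (short > 0) {
    extra <- order(raw - base, decreasing = TRUE)[seq_len(short)]
    base[extra] <- base[extra] + 1
  }
  as.integer(base)
}

#' Assign conformers to supercell copies
#'
#' The Monte Carlo system-construction step: every copy of the molecule in
#' an `N1 x N2 x N3` supercell (one copy per symmetry operator per cell)
#' resolves each conformer site to exactly one conformer. The default
#' `quota` method gives each conformer `round(N * occ)` copies via
#' largest-remainder apportionment — populations consistent with the
#' refined occupancies even at 32 copies — placed uniformly at random;
#' `multinomial` draws i.i.d. per copy.
#'
#' @param base A [xtal_structure()] with at least one conformer site.
#' @param dims Integer supercell dimensions, e.g. `c(2, 2, 2)`.
#' @param seed RNG seed; assignments are deterministic given the seed.
#' @param method `"quota"` (default) or `"multinomial"`.
#' @param exclude_sites Site ids assigned later (e.g. a conditional adduct).
#' @param absent_ok If `TRUE`, a site whose occupancies sum below 1 gains an
#'   implicit absent state; otherwise sums below 0.99 are an error.
#' @return A `supercell_model`: base structure, dims, per-copy table and the
#'   copy-by-site assignment (altloc `"-"` meaning absent).
#' @export
assign_conformers <- function(base, dims, seed = 1L,
                              method = c("quota", "multinomial"),
                              exclude_sites = character(), absent_ok = FALSE) {
  method <- match.arg(method)
  stopifnot(length(dims) == 3, all(dims >= 1))
  sites <- conformer_sites(base)
  sites <- dplyr::filter(sites, !.data$site %in% exclude_sites)
  if (!nrow(sites)) stop("structure has no conformer sites to assign", call. = FALSE)

  nop <- n_ops(base$spacegroup)
  lattice <- expand.grid(k = 0:(dims[3] - 1), j = 0:(dims[2] - 1),
                         i = 0:(dims[1] - 1))[, 3:1]
  # copies indexed (symmetry op, lattice vector) lexicographically
  copies <- tibble::tibble(
    copy = seq_len(nop * nrow(lattice)),
    op = rep(seq_len(nop), each = nrow(lattice)),
    i = rep(lattice$i, nop), j = rep(lattice$j, nop), k = rep(lattice$k, nop),
    adduct = FALSE
  )
  ncopy <- nrow(copies)

  set.seed(seed)
  assign <- list()
  for (sid in unique(sites$site)) {
    sub <- dplyr::filter(sites, .data$site == sid)
    occ <- sub$occ
    lab <- sub$altloc
    total <- sum(occ)
    if (total < 0.99 && !absent_ok) {
      stop("occupancies of site ", sid, " sum to ", round(total, 3),
           " with no absent conformer declared", call. = FALSE)
    }
    if (total < 1 - 1e-9 && absent_ok) {
      occ <- c(occ, 1 - total); lab <- c(lab, "-")
    }
    occ <- occ / sum(occ)
    if (method == "quota") {
      # global largest-remainder counts, dealt round-robin across symmetry-
      # operator strata so each crystallographic environment realizes the
      # occupancies as closely as integer counts allow; placement within a
      # stratum is uniformly random
      counts <- largest_remainder(occ, ncopy)
      pool <- rep(lab, counts)
      nstrata <- nop
      chosen <- character(ncopy)
      for (st in seq_len(nstrata)) {
        members <- copies$copy[copies$op == st]
        stratum_pool <- pool[seq_along(pool) %% nstrata == st %% nstrata]
        chosen[members] <- sample(stratum_pool)
      }
    } else {
      chosen <- sample(lab, ncopy, replace = TRUE, prob = occ)
    }
    assign[[sid]] <- tibble::tibble(copy = copies$copy, site = sid,
                                    altloc = chosen)
  }
  structure(list(
    base = base, dims = as.integer(dims), copies = copies,
    assignment = dplyr::bind_rows(assign), method = method, seed = seed
  ), class = "supercell_model")
}

#' @export
print.supercell_model <- function(x, ...) {
  cat(sprintf("<supercell_model> %d x %d x %d, %d copies, %d site(s), %d adduct(s)\n",
              x$dims[1], x$dims[2], x$dims[3], nrow(x$copies),
              length(unique(x$assignment$site)), sum(x$copies$adduct)))
  invisible(x)
}

#' Conditionally assign a covalent adduct
#'
#' Second Monte Carlo round: copies whose nucleophile site realized the
#' reactive conformer may carry the adduct; all other copies never do.
#' Quota places `round(n_reactive * p)` adducts uniformly at random among
#' reactive copies; multinomial flips an independent coin per reactive copy.
#'
#' @param model A `supercell_model` from [assign_conformers()].
#' @param p_adduct_given_reactive Conditional adduct probability in \[0,1\].
#' @param host_site Site id of the nucleophile side chain.
#' @param adduct_site Site id of the adduct atoms in the base structure
#'   (excluded from [assign_conformers()]); may be `NULL` when the base has
#'   no adduct atoms and only the flags are wanted.
#' @param reactive_altloc Altloc label of the reactive conformer (default "A").
#' @param seed RNG seed.
#' @param method `"quota"` or `"multinomial"`.
#' @return The model with its `copies$adduct` flags set.
#' @export
assign_adduct <- function(model, p_adduct_given_reactive, host_site,
                          adduct_site = NULL, reactive_altloc = "A", seed = 1L,
                          method = c("quota", "multinomial")) {
  method <- match.arg(method)
  p <- p_adduct_given_reactive
  stopifnot(p >= 0, p <= 1)
  hosts <- dplyr::filter(model$assignment, .data$site == host_site)
  if (!nrow(hosts)) stop("unknown host site: ", host_site, call. = FALSE)
  reactive <- hosts$copy[hosts$altloc == reactive_altloc]
  if (p > 0 && !length(reactive)) {
    warning("no copies realize the reactive conformer; no adducts assigned")
    return(model)
  }
  set.seed(seed)
  flag <- rep(FALSE, nrow(model$copies))
  if (p > 0 && length(reactive)) {
    if (method == "quota") {
      n_add <- round(length(reactive) * p)
      if (n_add > 0) {
        flag[sample(reactive, n_add)] <- TRUE
      }
    } else {
      flag[reactive] <- stats::runif(length(reactive)) < p
    }
  }
  model$copies$adduct <- flag
  model$adduct_site <- adduct_site
  model$host_site <- host_site
  model
}

#' Fraction of a host conformer carrying a modification
#'
#' From refined occupancies: an adduct at occupancy `occ_adduct` bonded to
#' a host conformer at occupancy `occ_host` means the host conformation is
#' `100 * occ_adduct / occ_host` percent modified.
#'
#' @param occ_adduct Adduct occupancy, `0 <= occ_adduct <= occ_host`.
#' @param occ_host Host conformer occupancy, in (0, 1].
#' @return Percent modified.
#' @examples
#' modification_fraction(0.53, 0.85)  # ~62
#' @export
modification_fraction <- function(occ_adduct, occ_host) {
  if (occ_host <= 0 || occ_host > 1) {
    stop("occ_host must lie in (0, 1]", call. = FALSE)
  }
  if (occ_adduct < 0 || occ_adduct > occ_host) {
    stop("occ_adduct must lie in [0, occ_host]", call. = FALSE)
  }
  100 * occ_adduct / occ_host
}

#' Ion counts from buffer concentrations and solvent volume
#'
#' `N = rounding(C * V * N_A)` per species, the bookkeeping used to match a
#' simulated solvent volume to a crystallization buffer. Counts are summed
#' over all buffer components contributing a species before rounding.
#'
#' @param concentrations Named numeric vector, mol/L per species.
#' @param solvent_volume Solvent volume in liters.
#' @param rounding `"nearest"` (default) or `"ceiling"`.
#' @return Tibble with columns `species`, `conc`, `count`.
#' @examples
#' ion_counts(c(MG = 0.125), 1.0379e-21)  # 78
#' @export
ion_counts <- function(concentrations, solvent_volume,
                       rounding = c("nearest", "ceiling")) {
  rounding <- match.arg(rounding)
  stopifnot(solvent_volume > 0)
  if (any(concentrations < 0)) stop("negative concentration", call. = FALSE)
  avogadro <- 6.022e23
  species <- names(concentrations)
  if (is.null(species)) stop("concentrations must be named by species", call. = FALSE)
  conc <- tapply(concentrations, species, sum)
  n <- unname(conc) * solvent_volume * avogadro
  count <- if (rounding == "nearest") round(n) else ceiling(n)
  tibble::tibble(species = names(conc), conc = unname(conc),
                 count = as.integer(count))
}

#' Realize a supercell model as an explicit structure
#'
#' Produces one explicit P1 atom set: cell lengths scaled by `dims`, every
#' copy placed by its symmetry operator and lattice translation, each site
#' reduced to its single assigned conformer, and all occupancies set to 1 —
#' the disorder formerly carried by occupancies is now explicit in the
#' population of copies.
#'
#' @param model A `supercell_model`.
#' @return A [xtal_structure()] in P1 with the supercell cell.
#' @export
realize <- function(model) {
  base <- model$base
  dims <- model$dims
  cl <- base$cell
  supercell <- unit_cell(cl$a * dims[1], cl$b * dims[2], cl$c * dims[3],
                         cl$alpha, cl$beta, cl$gamma)
  sites <- conformer_sites(base)
  a <- base$atoms
  # map each atom to its site (if any)
  akey <- rep(NA_character_, nrow(a))
  for (r in seq_len(nrow(sites))) {
    hit <- a$chain == sites$chain[r] & a$altloc == sites$altloc[r] &
      a$resid >= sites$resid_min[r] & a$resid <= sites$resid_max[r]
    akey[hit] <- sites$site[r]
  }
  adduct_site <- model$adduct_site
  pieces <- vector("list", nrow(model$copies))
  for (ci in seq_len(nrow(model$copies))) {
    cp <- model$copies[ci, ]
    chosen <- dplyr::filter(model$assignment, .data$copy == cp$copy)
    keep <- is.na(akey)
    for (r in seq_len(nrow(chosen))) {
      keep <- keep | (akey == chosen$site[r] & a$altloc == chosen$altloc[r] &
                        !is.na(akey))
    }
    if (!is.null(adduct_site)) {
      is_adduct <- !is.na(akey) & akey == adduct_site
      keep[is_adduct] <- cp$adduct
    }
    sub <- a[keep, ]
    op <- base$spacegroup$ops[[cp$op]]
    xyz <- as.matrix(sub[, c("fx", "fy", "fz")])
    xyz <- xyz %*% t(op$R) + matrix(op$t, nrow(sub), 3, byrow = TRUE)
    xyz <- sweep(xyz %% 1, 2, c(cp$i, cp$j, cp$k), "+")
    xyz <- sweep(xyz, 2, dims, "/")
    sub$fx <- xyz[, 1]; sub$fy <- xyz[, 2]; sub$fz <- xyz[, 3]
    if (cp$op > 1) {
      Rc <- op_cart_rotation(cl, op)
      for (i in seq_len(nrow(sub))) {
        U <- Rc %*% u_matrix(sub[i, ]) %*% t(Rc)
        sub$u11[i] <- U[1, 1]; sub$u22[i] <- U[2, 2]; sub$u33[i] <- U[3, 3]
        sub$u12[i] <- U[1, 2]; sub$u13[i] <- U[1, 3]; sub$u23[i] <- U[2, 3]
      }
    }
    sub$occ <- 1
    sub$altloc <- ""
    sub$chain <- sprintf("%s%03d", sub$chain, cp$copy)
    pieces[[ci]] <- sub
  }
  atoms <- dplyr::bind_rows(pieces)
  xtal_structure(supercell, spacegroup("P1"), atoms,
                 altgroups = infer_altgroups(atoms))
}

#' Realized conformer frequencies of a supercell model
#'
#' @param model A `supercell_model`.
#' @return Tibble `site`, `altloc`, `n`, `freq`.
#' @export
conformer_frequencies <- function(model) {
  model$assignment |>
    dplyr::count(.data$site, .data$altloc, name = "n") |>
    dplyr::group_by(.data$site) |>
    dplyr::mutate(freq = .data$n / sum(.data$n)) |>
    dplyr::ungroup()
}

#' Write a supercell realization manifest as JSON
#'
#' Records dims, seed, method and the per-copy conformer choices and adduct
#' flags, for reproducibility audits.
#'
#' @param model A `supercell_model`.
#' @param path Output JSON path.
#' @return Invisibly `path`.
#' @export
write_manifest <- function(model, path) {
  wide <- tidyr::pivot_wider(model$assignment, names_from = "site",
                             values_from = "altloc")
  jsonlite::write_json(list(
    dims = model$dims, seed = model$seed, method = model$method,
    copies = dplyr::left_join(model$copies, wide, by = "copy")
  ), path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
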