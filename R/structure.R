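#' Crystal structure container
#'
#' A `xtal_structure` bundles a unit cell, a space group and an atom table.
#' Atoms are stored as a tibble in fractional coordinates with anisotropic
#' displacement tensors (cartesian, Angstrom^2) as the primary ADP
#' representation; the isotropic B factor is derived as
#' `B = 8 pi^2 * trace(U) / 3`.
#'
#' Atom-table columns: `record` ("ATOM"/"HETATM"), `chain`, `resid`,
#' `resname`, `name`, `altloc` ("" when single-conformer), `element`,
#' `fx`, `fy`, `fz` (fractional), `occ`, `u11`,`u22`,`u33`,`u12`,`u13`,`u23`
#' (cartesian U, Angstrom^2) and `aniso` (whether the atom carries a genuine
#' anisotropic tensor rather than an isotropic one stored in U form).
#'
#' @param cell A [unit_cell()].
#' @param sg A [spacegroup()].
#' @param atoms Atom tibble (see Details).
#' @param altgroups Optional tibble of occupancy groups as produced by
#'   [infer_altgroups()]; inferred from the atom table when `NULL`.
#' @return An object of class `xtal_structure`.
#' @export
xtal_structure <- function(cell, sg, atoms, altgroups = NULL) {
  stopifnot(inherits(cell, "unit_cell"), inherits(sg, "spacegroup"))
  atoms <- as_atom_tibble(atoms)
  s <- structure(
    list(cell = cell, spacegroup = sg, atoms = atoms, altgroups = NULL),
    class = "xtal_structure"
  )
  s$altgroups <- if (is.null(altgroups)) infer_altgroups(s) else altgroups
  validate_structure(s)
  s
}

atom_cols <- c(
  "record", "chain", "resid", "resname", "name", "altloc", "element",
  "fx", "fy", "fz", "occ", "u11", "u22", "u33", "u12", "u13", "u23", "aniso"
)

as_atom_tibble <- function(atoms) {
  atoms <- tibble::as_tibble(atoms)
  if (!"record" %in% names(atoms)) atoms$record <- "ATOM"
  if (!"altloc" %in% names(atoms)) atoms$altloc <- ""
  if (!"aniso" %in% names(atoms)) atoms$aniso <- FALSE
  missing <- setdiff(atom_cols, names(atoms))
  if (length(missing)) {
    stop("atom table is missing columns: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  atoms[atom_cols]
}

#' @export
print.xtal_structure <- function(x, ...) {
  cat(sprintf(
    "<xtal_structure> %d atoms, %s, cell %.1f x %.1f x %.1f A, %d altgroup(s)\n",
    nrow(x$atoms), x$spacegroup$symbol, x$cell$a, x$cell$b, x$cell$c,
    nrow(x$altgroups)
  ))
  invisible(x)
}

#' Isotropic B factors derived from U tensors
#'
#' @param s A [xtal_structure()] or an atom tibble.
#' @return Numeric vector, `8 pi^2 * trace(U)/3` per atom (Angstrom^2).
#' @export
biso <- function(s) {
  a <- if (inherits(s, "xtal_structure")) s$atoms else s
  8 * pi^2 * (a$u11 + a$u22 + a$u33) / 3
}

#' Build an isotropic U tensor column set from B factors
#' @param b Numeric vector of isotropic B factors (Angstrom^2).
#' @return Tibble with columns u11..u23 for `U = (B / 8 pi^2) I`.
#' @export
u_from_biso <- function(b) {
  u <- b / (8 * pi^2)
  tibble::tibble(u11 = u, u22 = u, u33 = u,
                 u12 = 0 * u, u13 = 0 * u, u23 = 0 * u)
}

# n x 6 -> list of symmetric 3x3 matrices is avoided; helpers work on columns
u_matrix <- function(row) {
  matrix(c(row$u11, row$u12, row$u13,
           row$u12, row$u22, row$u23,
           row$u13, row$u23, row$u33), 3, 3)
}

#' Cartesian coordinates of the atom table
#' @param s A [xtal_structure()].
#' @return n x 3 matrix of cartesian coordinates (Angstrom).
#' @export
atoms_cart <- function(s) {
  frac_to_cart(s$cell, as.matrix(s$atoms[, c("fx", "fy", "fz")]))
}

# electron counts for the supported elements
element_z <- c(
  H = 1, C = 6, N = 7, O = 8, NA_ = 11, MG = 12, P = 15, S = 16,
  CL = 17, K = 19, CA = 20, FE = 26
)

#' Electron count per element symbol
#' @param element Character vector of element symbols.
#' @return Integer electron counts.
#' @export
electron_count <- function(element) {
  key <- toupper(element)
  key[key == "NA"] <- "NA_"
  z <- element_z[key]
  if (anyNA(z)) {
    stop("unknown element(s): ", paste(unique(element[is.na(z)]), collapse = ", "),
         call. = FALSE)
  }
  unname(z)
}

#' Total coherent scattering of a structure
#'
#' Occupancy-weighted electron count, the quantity conserved by symmetry
#' expansion (up to operator multiplicity) and by supercell realization.
#'
#' @param s A [xtal_structure()].
#' @return Scalar, sum over atoms of `occ * Z`.
#' @export
total_scattering <- function(s) {
  sum(s$atoms$occ * electron_count(s$atoms$element))
}

#' Infer occupancy groups from alternate-conformer labels
#'
#' Atoms sharing a chain, an altloc label and a common occupancy over a
#' contiguous run of residues form one group (the coordinate formats do not
#' encode grouped-occupancy refinement, so grouping is reconstructed from
#' the shared label + equal occupancy).
#'
#' @param s A [xtal_structure()] or atom tibble.
#' @return Tibble with columns `group`, `chain`, `altloc`, `resid_min`,
#'   `resid_max`, `occ`, `n_atoms`.
#' @export
infer_altgroups <- function(s) {
  a <- if (inherits(s, "xtal_structure")) s$atoms else tibble::as_tibble(s)
  alt <- dplyr::filter(a, .data$altloc != "")
  if (nrow(alt) == 0) {
    return(tibble::tibble(group = character(), chain = character(),
                          altloc = character(), resid_min = integer(),
                          resid_max = integer(), occ = double(),
                          n_atoms = integer()))
  }
  per_res <- alt |>
    dplyr::group_by(.data$chain, .data$altloc, .data$resid, .data$occ) |>
    dplyr::summarise(n_atoms = dplyr::n(), .groups = "drop") |>
    dplyr::arrange(.data$chain, .data$altloc, .data$resid)
  per_res |>
    dplyr::group_by(.data$chain, .data$altloc, .data$occ) |>
    dplyr::mutate(run = cumsum(c(1L, diff(.data$resid) != 1L))) |>
    dplyr::group_by(.data$chain, .data$altloc, .data$occ, .data$run) |>
    dplyr::summarise(resid_min = min(.data$resid), resid_max = max(.data$resid),
                     n_atoms = sum(.data$n_atoms), .groups = "drop") |>
    dplyr::arrange(.data$chain, .data$resid_min, .data$altloc) |>
    dplyr::mutate(group = sprintf("%s:%d-%d:%s", .data$chain, .data$resid_min,
                                  .data$resid_max, .data$altloc)) |>
    dplyr::select("group", "chain", "altloc", "resid_min", "resid_max",
                  "occ", "n_atoms")
}

#' Validate structure invariants
#'
#' Checks occupancies in \[0,1\], positive semidefinite anisotropic tensors,
#' altloc occupancy sums at most 1 per atom site, and that altgroup members
#' share their occupancy exactly.
#'
#' @param s A [xtal_structure()].
#' @return Invisibly `TRUE`; errors on violation.
#' @export
validate_structure <- function(s) {
  a <- s$atoms
  if (any(a$occ < -1e-9 | a$occ > 1 + 1e-9)) {
    stop("occupancies must lie in [0, 1]", call. = FALSE)
  }
  bad_u <- which(a$aniso & vapply(seq_len(nrow(a)), function(i) {
    min(eigen(u_matrix(a[i, ]), symmetric = TRUE, only.values = TRUE)$values) < -1e-8
  }, TRUE))
  if (length(bad_u)) {
    stop("anisotropic U tensor not positive semidefinite for atom row(s) ",
         paste(utils::head(bad_u, 5), collapse = ", "), call. = FALSE)
  }
  sums <- a |>
    dplyr::filter(.data$altloc != "") |>
    dplyr::group_by(.data$chain, .data$resid, .data$name) |>
    dplyr::summarise(total = sum(.data$occ), .groups = "drop")
  if (any(sums$total > 1 + 1e-6)) {
    stop("altloc occupancies of one atom site sum to > 1", call. = FALSE)
  }
  if (nrow(s$altgroups)) {
    for (i in seq_len(nrow(s$altgroups))) {
      g <- s$altgroups[i, ]
      members <- dplyr::filter(
        a, .data$chain == g$chain, .data$altloc == g$altloc,
        .data$resid >= g$resid_min, .data$resid <= g$resid_max
      )
      if (nrow(members) && any(abs(members$occ - g$occ) > 1e-9)) {
        stop("altgroup ", g$group, " members do not share one occupancy",
             call. = FALSE)
      }
    }
  }
  invisible(TRUE)
}

# cartesian rotation matrix of a fractional-space operator
op_cart_rotation <- function(cell, op) {
  cell$orth %*% op$R %*% cell$frac
}

#' Expand a structure to the full unit cell (P1)
#'
#' Replicates every asymmetric-unit atom under all space-group operators,
#' rotating anisotropic U tensors accordingly, and wraps fractional
#' coordinates to `[0, 1)`. The result is in space group P1 with
#' `n_ops * n_atoms` atoms.
#'
#' @param s A [xtal_structure()].
#' @return A [xtal_structure()] in P1.
#' @export
expand_to_unit_cell <- function(s) {
  ops <- s$spacegroup$ops
  if (length(ops) == 1) {
    out <- s
    wrapped <- as.matrix(out$atoms[, c("fx", "fy", "fz")]) %% 1
    out$atoms$fx <- wrapped[, 1]
    out$atoms$fy <- wrapped[, 2]
    out$atoms$fz <- wrapped[, 3]
    out$spacegroup <- spacegroup("P1")
    return(out)
  }
  pieces <- lapply(seq_along(ops), function(k) {
    op <- ops[[k]]
    a <- s$atoms
    xyz <- as.matrix(a[, c("fx", "fy", "fz")])
    new_xyz <- (xyz %*% t(op$R) + matrix(op$t, nrow(a), 3, byrow = TRUE)) %% 1
    a$fx <- new_xyz[, 1]; a$fy <- new_xyz[, 2]; a$fz <- new_xyz[, 3]
    Rc <- op_cart_rotation(s$cell, op)
    if (any(a$aniso) || any(abs(a$u12) > 0 | abs(a$u13) > 0 | abs(a$u23) > 0) ||
        any(a$u11 != a$u22 | a$u11 != a$u33)) {
      for (i in seq_len(nrow(a))) {
        U <- Rc %*% u_matrix(a[i, ]) %*% t(Rc)
        a$u11[i] <- U[1, 1]; a$u22[i] <- U[2, 2]; a$u33[i] <- U[3, 3]
        a$u12[i] <- U[1, 2]; a$u13[i] <- U[1, 3]; a$u23[i] <- U[2, 3]
      }
    }
    a$chain <- paste0(a$chain, if (k == 1) "" else as.character(k))
    a
  })
  atoms <- dplyr::bind_rows(pieces)
  xtal_structure(s$cell, spacegroup("P1"), atoms)
}

#' Filter the atoms of a structure
#'
#' Convenience wrapper applying a dplyr filter expression to the atom table
#' while keeping the structure class.
#'
#' @param s A [xtal_structure()].
#' @param ... Passed to [dplyr::filter()] on the atom table.
#' @return A [xtal_structure()] with the filtered atoms.
#' @export
filter_atoms <- function(s, ...) {
  out <- s
  out$atoms <- dplyr::filter(s$atoms, ...)
  out$altgroups <- infer_altgroups(out)
  out
}

# main-chain atom names for the toy chemistry and standard models
mainchain_names <- c("N", "CA", "C", "O")

#' Atom selection helpers
#'
#' `select_mainchain()` keeps N/CA/C/O atoms; `select_residues()` keeps a
#' residue range; `select_component()` keeps protein (`ATOM` records), water
#' (`HOH`/`WAT` residues) or a single-element ion species.
#'
#' @param s A [xtal_structure()].
#' @param from,to Residue range bounds (inclusive).
#' @param component One of `"all"`, `"protein"`, `"water"` or an element
#'   symbol such as `"MG"`.
#' @return A filtered [xtal_structure()].
#' @export
select_mainchain <- function(s) filter_atoms(s, .data$name %in% mainchain_names)

#' @rdname select_mainchain
#' @export
select_residues <- function(s, from, to) {
  filter_atoms(s, .data$resid >= from, .data$resid <= to)
}

#' @rdname select_mainchain
#' @export
select_component <- function(s, component = "all") {
  out <- switch(tolower(component),
    all = s,
    protein = filter_atoms(s, .data$record == "ATOM"),
    water = filter_atoms(s, .data$resname %in% c("HOH", "WAT")),
    filter_atoms(s, toupper(.data$element) == toupper(component),
                 .data$record == "HETATM")
  )
  if (nrow(out$atoms) == 0) {
    stop("selection '", component, "' matches no atoms", call. = FALSE)
  }
  out
}
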