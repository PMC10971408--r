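#' Per-residue B-factor differences
#'
#' `B_diff = B_on - B_off` averaged over the selected atoms of each
#' residue, matching residues by chain/number/atom name. When alternates
#' exist, the altloc "A" conformer (typically the most occupied) is used;
#' single-conformer atoms always match. Unmatched residues are listed in a
#' warning and skipped.
#'
#' @param s_on,s_off [xtal_structure()]s with matched residue numbering.
#' @param selection `"mainchain"` (default) or `"all"`.
#' @return Tibble (class `residue_profile`) with `chain`, `resid`, `value`
#'   (Angstrom^2).
#' @export
residue_bdiff <- function(s_on, s_off, selection = "mainchain") {
  pick <- function(s) {
    sel <- if (identical(selection, "mainchain")) select_mainchain(s) else s
    a <- sel$atoms
    a <- dplyr::filter(a, .data$altloc %in% c("", "A"))
    a$b <- biso(a)
    a[, c("chain", "resid", "name", "b")]
  }
  m <- dplyr::inner_join(pick(s_on), pick(s_off),
                         by = c("chain", "resid", "name"),
                         suffix = c("_on", "_off"))
  if (!nrow(m)) stop("no matching atoms between the two structures", call. = FALSE)
  all_res <- dplyr::distinct(pick(s_on)[, c("chain", "resid")])
  got_res <- dplyr::distinct(m[, c("chain", "resid")])
  missed <- dplyr::anti_join(all_res, got_res, by = c("chain", "resid"))
  if (nrow(missed)) {
    warning("unmatched residue(s) skipped: ",
            paste(sprintf("%s%d", missed$chain, missed$resid), collapse = ", "))
  }
  out <- m |>
    dplyr::group_by(.data$chain, .data$resid) |>
    dplyr::summarise(value = mean(.data$b_on - .data$b_off), .groups = "drop")
  class(out) <- c("residue_profile", class(out))
  out
}

#' Principal axes of an ADP ellipsoid
#'
#' Eigen-decomposition of a symmetric cartesian U tensor: eigenvalues
#' sorted descending with a deterministic sign convention (the largest-
#' magnitude component of each axis is positive).
#'
#' @param U Symmetric 3x3 matrix (Angstrom^2).
#' @return An `adp_ellipsoid`: `U`, `eigenvalues`, `axes` (columns are unit
#'   eigenvectors).
#' @export
principal_axes <- function(U) {
  if (!is.matrix(U) || any(dim(U) != 3) || max(abs(U - t(U))) > 1e-8) {
    stop("U must be a symmetric 3x3 matrix", call. = FALSE)
  }
  e <- eigen((U + t(U)) / 2, symmetric = TRUE)
  ord <- order(e$values, decreasing = TRUE)
  vals <- e$values[ord]
  vecs <- e$vectors[, ord, drop = FALSE]
  for (j in 1:3) {
    i <- which.max(abs(vecs[, j]))
    if (vecs[i, j] < 0) vecs[, j] <- -vecs[, j]
  }
  structure(list(U = U, eigenvalues = vals, axes = vecs),
            class = "adp_ellipsoid")
}

#' @export
print.adp_ellipsoid <- function(x, ...) {
  cat("<adp_ellipsoid> eigenvalues (A^2):",
      paste(sprintf("%.4f", x$eigenvalues), collapse = ", "), "\n")
  invisible(x)
}

#' Alignment of a difference-peak pair with ADP principal axes
#'
#' For a paired positive/negative difference peak flanking an atom, the
#' absolute cosine between the peak-pair displacement vector and the major
#' principal axis of the atom's ADP ellipsoid — near 1 when the apparent
#' atomic shift runs along the preferred direction of motion. The best
#' alignment over all three axes is also reported.
#'
#' @param peak_plus,peak_minus Cartesian positions (length-3 vectors).
#' @param u Atom U tensor: symmetric 3x3 matrix, or a one-row atom tibble.
#' @return List with `cos_major`, `cos_best`, `best_axis`.
#' @export
peak_axis_alignment <- function(peak_plus, peak_minus, u) {
  if (!is.matrix(u)) u <- u_matrix(u)
  v <- as.numeric(peak_plus) - as.numeric(peak_minus)
  nv <- sqrt(sum(v^2))
  if (nv < 1e-9) stop("coincident peaks", call. = FALSE)
  v <- v / nv
  ax <- principal_axes(u)$axes
  cosines <- abs(drop(v %*% ax))
  list(cos_major = cosines[1], cos_best = max(cosines),
       best_axis = which.max(cosines))
}

#' Rosenfield rigid-body difference matrix
#'
#' For every ordered pair of selected atoms, both U tensors are projected
#' on the unit interatomic vector `n`:
#' `Delta_AB = n' U_A n - n' U_B n` (Angstrom^2). For a rigid body the
#' projections are equal and the matrix vanishes; the matrix is exactly
#' antisymmetric by construction. A residue-binned reduction averages
#' `|Delta|` within bin pairs (default 30 bins, clipped to the residue
#' count).
#'
#' @param s A [xtal_structure()].
#' @param selection `"mainchain"` (default) or `"all"`.
#' @param bins Number of residue bins for the reduction.
#' @return A `rosenfield_matrix`: atom-level `delta` matrix, `binned`
#'   matrix of mean `|Delta|`, atom metadata and bin assignments.
#' @export
rosenfield <- function(s, selection = "mainchain", bins = 30) {
  sel <- if (identical(selection, "mainchain")) select_mainchain(s) else s
  sel <- filter_atoms(sel, .data$altloc %in% c("", "A"))
  a <- sel$atoms
  if (!nrow(a)) stop("empty selection", call. = FALSE)
  if (!all(a$aniso)) {
    warning("isotropic atoms present; using U = (B / 8 pi^2) I for them")
  }
  cart <- atoms_cart(sel)
  n <- nrow(a)
  u6 <- as.matrix(a[, c("u11", "u22", "u33", "u12", "u13", "u23")])
  delta <- matrix(0, n, n)
  for (i in seq_len(n)) {
    d <- sweep(cart, 2, cart[i, ], "-")
    len <- sqrt(rowSums(d^2))
    len[i] <- 1
    nv <- d / len
    # projection of each atom's U on the i->j unit vector
    proj_j <- nv[, 1]^2 * u6[, 1] + nv[, 2]^2 * u6[, 2] + nv[, 3]^2 * u6[, 3] +
      2 * nv[, 1] * nv[, 2] * u6[, 4] + 2 * nv[, 1] * nv[, 3] * u6[, 5] +
      2 * nv[, 2] * nv[, 3] * u6[, 6]
    proj_i <- nv[, 1]^2 * u6[i, 1] + nv[, 2]^2 * u6[i, 2] +
      nv[, 3]^2 * u6[i, 3] + 2 * nv[, 1] * nv[, 2] * u6[i, 4] +
      2 * nv[, 1] * nv[, 3] * u6[i, 5] + 2 * nv[, 2] * nv[, 3] * u6[i, 6]
    delta[i, ] <- proj_i - proj_j
    delta[i, i] <- 0
  }
  nbin <- min(bins, length(unique(a$resid)))
  bin_of <- as.integer(cut(match(a$resid, sort(unique(a$resid))),
                           breaks = nbin, labels = FALSE))
  binned <- matrix(0, nbin, nbin)
  for (p in seq_len(nbin)) for (q in seq_len(nbin)) {
    rows <- which(bin_of == p); cols <- which(bin_of == q)
    block <- abs(delta[rows, cols, drop = FALSE])
    if (p == q) {
      off <- block[upper.tri(block) | lower.tri(block)]
      binned[p, q] <- if (length(off)) mean(off) else 0
    } else {
      binned[p, q] <- mean(block)
    }
  }
  structure(list(delta = delta, binned = binned, bins = nbin,
                 atoms = a[, c("chain", "resid", "name")], bin_of = bin_of),
            class = "rosenfield_matrix")
}

#' @export
print.rosenfield_matrix <- function(x, ...) {
  cat(sprintf("<rosenfield_matrix> %d atoms, %d bins, mean |Delta| = %.5f A^2\n",
              nrow(x$atoms), x$bins, mean(abs(x$delta))))
  invisible(x)
}

#' Rigid-body test on a Rosenfield matrix
#'
#' @param rm A `rosenfield_matrix`.
#' @param tol Pass criterion on the binned mean `|Delta|` (Angstrom^2,
#'   default 0.001).
#' @return Logical: does the selection move as one rigid body?
#' @export
is_rigid_body <- function(rm, tol = 0.001) {
  mean(rm$binned) < tol
}
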