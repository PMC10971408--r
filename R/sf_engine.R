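#' Structure factors by direct summation
#'
#' Exact Debye-Waller-damped direct summation over all atoms and symmetry
#' operators:
#' `F(h) = sum_ops sum_atoms occ * f(s) * DW(h; U) * exp(2 pi i h.(Rx + t))`
#' with the anisotropic Debye-Waller factor `exp(-2 pi^2 s' U s)` evaluated
#' on the cartesian reciprocal vector `s` (|s| = 1/d). This is the oracle
#' path for all other structure-factor code.
#'
#' @param s A [xtal_structure()].
#' @param hkl Integer matrix of Miller indices (n x 3), or `NULL` to
#'   generate the Friedel-unique set to `dmin`.
#' @param dmin Resolution cutoff used when `hkl` is `NULL`.
#' @return A [reflection_set()] with complex column `F`.
#' @export
sf_direct <- function(s, hkl = NULL, dmin = NULL) {
  if (is.null(hkl)) {
    if (is.null(dmin)) stop("provide either hkl or dmin", call. = FALSE)
    hkl <- miller_indices(s$cell, dmin)
  }
  if (!is.matrix(hkl)) hkl <- matrix(hkl, ncol = 3)
  sx <- if (n_ops(s$spacegroup) > 1) expand_to_unit_cell(s) else s
  a <- sx$atoms
  Fv <- sf_sum(
    cell = s$cell, hkl = hkl,
    frac = as.matrix(a[, c("fx", "fy", "fz")]),
    element = a$element, occ = a$occ,
    u6 = t(as.matrix(a[, c("u11", "u22", "u33", "u12", "u13", "u23")]))
  )
  reflection_set(s$cell, tibble::tibble(h = hkl[, 1], k = hkl[, 2],
                                        l = hkl[, 3], F = Fv),
                 dmin = min(d_spacing(s$cell, hkl)))
}

# core vectorized sum; u6 is 6 x natoms (u11,u22,u33,u12,u13,u23) or NULL
# for B = 0. Chunks reflections to bound memory.
sf_sum <- function(cell, hkl, frac, element, occ, u6 = NULL, chunk = 512L) {
  key <- ff_lookup(element)
  uelem <- unique(key)
  eidx <- match(key, uelem)
  n <- nrow(hkl)
  Fv <- complex(n)
  for (start in seq(1L, n, by = chunk)) {
    rows <- start:min(start + chunk - 1L, n)
    hb <- hkl[rows, , drop = FALSE]
    sv <- recip_vectors(cell, hb)
    smag <- sqrt(rowSums(sv^2))
    fmat <- form_factor(sub("_$", "", uelem), smag)   # nrow x nelem
    coef <- fmat[, eidx, drop = FALSE] *
      matrix(occ, length(rows), length(occ), byrow = TRUE)
    if (!is.null(u6)) {
      S6 <- cbind(sv[, 1]^2, sv[, 2]^2, sv[, 3]^2,
                  2 * sv[, 1] * sv[, 2], 2 * sv[, 1] * sv[, 3],
                  2 * sv[, 2] * sv[, 3])
      coef <- coef * exp(-2 * pi^2 * (S6 %*% u6))
    }
    ph <- hb %*% t(frac)
    Fv[rows] <- rowSums(coef * exp(2i * pi * ph))
  }
  Fv
}

#' Structure factors via FFT of a sampled density
#'
#' Samples ADP-broadened Gaussian atoms on a cell-commensurate grid
#' (default spacing `dmin / 3`, Gaussians truncated at 4.5 sigma) and
#' Fourier-analyses the grid. Agrees with [sf_direct()] to an
#' amplitude-weighted relative error below 1% at the default grid rule for
#' typical ADPs.
#'
#' @param s A [xtal_structure()].
#' @param dmin Resolution cutoff (Angstrom).
#' @param grid_rule Grid spacing as a fraction of `dmin` (default 1/3).
#' @return A [reflection_set()] with complex column `F`.
#' @export
sf_fft <- function(s, dmin, grid_rule = 1 / 3) {
  stopifnot(dmin > 0)
  if (grid_rule > 0.5) {
    stop("grid too coarse for dmin: grid_rule must be <= 0.5 (Nyquist)",
         call. = FALSE)
  }
  dims <- grid_dim_for(s$cell, dmin, grid_rule)
  g <- sample_density(s, dims)
  hkl <- miller_indices(s$cell, dmin)
  Farr <- stats::fft(g$values, inverse = TRUE) * s$cell$volume / prod(dims)
  idx <- cbind(hkl[, 1] %% dims[1], hkl[, 2] %% dims[2], hkl[, 3] %% dims[3]) + 1
  Fv <- Farr[idx]
  reflection_set(s$cell, tibble::tibble(h = hkl[, 1], k = hkl[, 2],
                                        l = hkl[, 3], F = Fv),
                 dmin = min(d_spacing(s$cell, hkl)))
}

#' Sample a structure's electron density on a grid
#'
#' Each form-factor Gaussian term becomes a real-space Gaussian with
#' covariance `U + (b_i / 8 pi^2) I`; the constant term uses the ADP alone.
#' Symmetry mates are expanded first; density wraps periodically.
#'
#' @param s A [xtal_structure()].
#' @param dims Integer grid dimensions (length 3).
#' @param truncate Gaussian truncation radius in sigma units (default 4.5).
#' @return A [density_grid()] in electrons per cubic Angstrom.
#' @export
sample_density <- function(s, dims, truncate = 4.5) {
  sx <- if (n_ops(s$spacegroup) > 1) expand_to_unit_cell(s) else s
  a <- sx$atoms
  cell <- s$cell
  tab <- ff_table()
  key <- ff_lookup(a$element)
  rho <- array(0, dim = dims)
  frac_rownorm <- sqrt(rowSums(cell$frac^2))  # frac extent per cartesian A
  two_pi2 <- 8 * pi^2
  for (i in seq_len(nrow(a))) {
    co <- tab[[key[i]]]
    U <- u_matrix(a[i, ])
    terms_a <- c(co$a, co$c)
    terms_b <- c(co$b, 0)
    keep <- abs(terms_a) > 1e-8
    terms_a <- terms_a[keep]; terms_b <- terms_b[keep]
    sigmas <- lapply(terms_b, function(b) U + diag(3) * (b / two_pi2))
    lam_max <- max(vapply(sigmas, function(S)
      max(eigen(S, symmetric = TRUE, only.values = TRUE)$values), 0))
    if (lam_max <= 1e-6) {
      stop("sample_density requires non-zero ADPs (atom row ", i, ")",
           call. = FALSE)
    }
    rcut <- truncate * sqrt(lam_max)
    ctr <- c(a$fx[i], a$fy[i], a$fz[i])
    half <- ceiling(rcut * frac_rownorm * dims)
    ctr_idx <- round(ctr * dims)
    gx <- (ctr_idx[1] - half[1]):(ctr_idx[1] + half[1])
    gy <- (ctr_idx[2] - half[2]):(ctr_idx[2] + half[2])
    gz <- (ctr_idx[3] - half[3]):(ctr_idx[3] + half[3])
    pts <- cbind(
      rep.int(gx, length(gy) * length(gz)),
      rep.int(rep(gy, each = length(gx)), length(gz)),
      rep(gz, each = length(gx) * length(gy))
    )
    dfrac <- sweep(pts / matrix(dims, nrow(pts), 3, byrow = TRUE), 2, ctr)
    D <- dfrac %*% t(cell$orth)
    r2 <- rowSums(D^2)
    near <- r2 <= rcut^2
    if (!any(near)) next
    D <- D[near, , drop = FALSE]
    val <- numeric(nrow(D))
    for (j in seq_along(terms_a)) {
      Sj <- sigmas[[j]]
      Sinv <- solve(Sj)
      q <- rowSums((D %*% Sinv) * D)
      val <- val + terms_a[j] * (2 * pi)^(-1.5) / sqrt(det(Sj)) * exp(-0.5 * q)
    }
    idx <- cbind(pts[near, 1] %% dims[1], pts[near, 2] %% dims[2],
                 pts[near, 3] %% dims[3]) + 1
    lin <- idx[, 1] + dims[1] * (idx[, 2] - 1) + dims[1] * dims[2] * (idx[, 3] - 1)
    add <- a$occ[i] * val
    # accumulate with possible duplicate linear indices after wrapping
    acc <- rowsum(add, lin)
    rho[as.integer(rownames(acc))] <- rho[as.integer(rownames(acc))] + acc[, 1]
  }
  density_grid(cell, rho)
}

#' Synthesize a density map from complex structure factors
#'
#' Inverse Fourier synthesis `rho(x) = (1/V) sum_h F(h) exp(-2 pi i h.x)`
#' with Friedel mates filled in from the stored hemisphere. `F(000)` is
#' omitted, so difference maps have mean ~ 0.
#'
#' @param r A [reflection_set()] with complex column `F`.
#' @param shape Grid dimensions; defaults to the `dmin/3` rule.
#' @return A [density_grid()].
#' @export
map_from_sf <- function(r, shape = NULL) {
  if (!"F" %in% names(r$tbl)) {
    stop("reflection set has amplitudes only; supply phases ",
         "(e.g. via sf_direct/sf_fft of a phasing model)", call. = FALSE)
  }
  if (is.null(shape)) shape <- grid_dim_for(r$cell, r$dmin)
  hkl <- as.matrix(r$tbl[, c("h", "k", "l")])
  nyq <- floor(shape / 2)
  if (any(abs(hkl[, 1]) > nyq[1] | abs(hkl[, 2]) > nyq[2] |
          abs(hkl[, 3]) > nyq[3])) {
    stop("grid shape too small for the reflection set", call. = FALSE)
  }
  Farr <- array(0i, dim = shape)
  put <- function(h, val) {
    idx <- cbind(h[, 1] %% shape[1], h[, 2] %% shape[2], h[, 3] %% shape[3]) + 1
    Farr[idx] <<- val
  }
  put(hkl, r$tbl$F)
  put(-hkl, Conj(r$tbl$F))
  rho <- Re(stats::fft(Farr)) / r$cell$volume
  density_grid(r$cell, rho)
}

#' Amplitude-weighted relative difference between two reflection sets
#'
#' `R = sum ||F_a| - |F_b|| / sum |F_a|` over common indices — the metric
#' used to compare the FFT and direct-summation paths.
#'
#' @param ra,rb [reflection_set()] objects on the same indices.
#' @return Scalar R value.
#' @export
r_factor <- function(ra, rb) {
  m <- dplyr::inner_join(
    tibble::tibble(h = ra$tbl$h, k = ra$tbl$k, l = ra$tbl$l, fa = amplitudes(ra)),
    tibble::tibble(h = rb$tbl$h, k = rb$tbl$k, l = rb$tbl$l, fb = amplitudes(rb)),
    by = c("h", "k", "l")
  )
  if (!nrow(m)) stop("no common reflections", call. = FALSE)
  sum(abs(m$fa - m$fb)) / sum(abs(m$fa))
}
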