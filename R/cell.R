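#' Unit cell
#'
#' Construct a crystallographic unit cell from lengths (Angstrom) and angles
#' (degrees). The orthogonalization matrix follows the standard convention:
#' `a` along x, `b` in the xy-plane.
#'
#' @param a,b,c Cell edge lengths in Angstrom. Must be positive.
#' @param alpha,beta,gamma Cell angles in degrees, each in (0, 180).
#' @return An object of class `unit_cell` with fields `a`, `b`, `c`, `alpha`,
#'   `beta`, `gamma`, the 3x3 orthogonalization matrix `orth` (fractional to
#'   cartesian), its inverse `frac` and the cell volume `volume` (cubic
#'   Angstrom).
#' @examples
#' cl <- unit_cell(25, 20, 18)
#' cl$volume
#' frac_to_cart(cl, c(0.5, 0.5, 0.5))
#' @export
unit_cell <- function(a, b, c, alpha = 90, beta = 90, gamma = 90) {
  stopifnot(is.numeric(a), is.numeric(b), is.numeric(c))
  if (any(c(a, b, c) <= 0)) {
    stop("unit cell lengths must be positive", call. = FALSE)
  }
  if (any(c(alpha, beta, gamma) <= 0) || any(c(alpha, beta, gamma) >= 180)) {
    stop("unit cell angles must lie in (0, 180) degrees", call. = FALSE)
  }
  ca <- cos(alpha * pi / 180); cb <- cos(beta * pi / 180); cg <- cos(gamma * pi / 180)
  sg <- sin(gamma * pi / 180)
  v2 <- 1 - ca^2 - cb^2 - cg^2 + 2 * ca * cb * cg
  if (v2 <= 0) stop("degenerate unit cell: angles give non-positive volume", call. = FALSE)
  vfac <- sqrt(v2)
  orth <- matrix(c(
    a, b * cg, c * cb,
    0, b * sg, c * (ca - cb * cg) / sg,
    0, 0,      c * vfac / sg
  ), nrow = 3, byrow = TRUE)
  structure(list(
    a = a, b = b, c = c, alpha = alpha, beta = beta, gamma = gamma,
    orth = orth, frac = solve(orth), volume = a * b * c * vfac
  ), class = "unit_cell")
}

#' @export
print.unit_cell <- function(x, ...) {
  cat(sprintf(
    "<unit_cell> a=%.3f b=%.3f c=%.3f alpha=%.2f beta=%.2f gamma=%.2f V=%.1f A^3\n",
    x$a, x$b, x$c, x$alpha, x$beta, x$gamma, x$volume
  ))
  invisible(x)
}

#' Fractional to cartesian coordinates
#'
#' @param cell A [unit_cell()].
#' @param frac Numeric vector of length 3 or an n x 3 matrix of fractional
#'   coordinates.
#' @return Cartesian coordinates (Angstrom), same shape as the input.
#' @export
frac_to_cart <- function(cell, frac) {
  stopifnot(inherits(cell, "unit_cell"))
  if (is.matrix(frac)) {
    t(cell$orth %*% t(frac))
  } else {
    drop(cell$orth %*% frac)
  }
}

#' Cartesian to fractional coordinates
#'
#' @inheritParams frac_to_cart
#' @param cart Numeric vector of length 3 or an n x 3 matrix of cartesian
#'   coordinates (Angstrom).
#' @return Fractional coordinates, same shape as the input.
#' @export
cart_to_frac <- function(cell, cart) {
  stopifnot(inherits(cell, "unit_cell"))
  if (is.matrix(cart)) {
    t(cell$frac %*% t(cart))
  } else {
    drop(cell$frac %*% cart)
  }
}

#' Resolution of Miller indices
#'
#' d-spacing (Angstrom) of reflections `h` in a given cell, via the
#' reciprocal-space metric.
#'
#' @param cell A [unit_cell()].
#' @param hkl Integer matrix (n x 3) of Miller indices.
#' @return Numeric vector of d-spacings in Angstrom.
#' @export
d_spacing <- function(cell, hkl) {
  if (!is.matrix(hkl)) hkl <- matrix(hkl, ncol = 3)
  # reciprocal cartesian vector s = (M^-1)^T h, |s| = 1/d
  s <- hkl %*% cell$frac  # rows: h %*% frac = t(t(frac) %*% h)
  1 / sqrt(rowSums(s^2))
}

# reciprocal cartesian scattering vectors, rows of length |s| = 1/d
recip_vectors <- function(cell, hkl) {
  if (!is.matrix(hkl)) hkl <- matrix(hkl, ncol = 3)
  hkl %*% cell$frac
}
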