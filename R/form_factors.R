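#' X-ray atomic form factors
#'
#' Four-Gaussian-plus-constant parameterization of the coherent x-ray
#' scattering factor, `f(s) = sum_i a_i exp(-b_i s^2 / 4) + c` with
#' `s = 1/d` (International Tables vol. C style coefficients). Built-in
#' entries cover the toy chemistry and the crystallization-buffer species
#' (H, C, N, O, S plus Mg, Cl, K and a few common extras); additional
#' elements can be registered per session.
#'
#' @format Internal named list: element -> list(a, b, c).
#' @name form_factors
NULL

.ff_builtin <- list(
  H  = list(a = c(0.493002, 0.322912, 0.140191, 0.040810),
            b = c(10.5109, 26.1257, 3.14236, 57.7997), c = 0.003038),
  C  = list(a = c(2.31000, 1.02000, 1.58860, 0.865000),
            b = c(20.8439, 10.2075, 0.568700, 51.6512), c = 0.215600),
  N  = list(a = c(12.2126, 3.13220, 2.01250, 1.16630),
            b = c(0.005700, 9.89330, 28.9975, 0.582600), c = -11.5290),
  O  = list(a = c(3.04850, 2.28680, 1.54630, 0.867000),
            b = c(13.2771, 5.70110, 0.323900, 32.9089), c = 0.250800),
  NA_ = list(a = c(4.76260, 3.17360, 1.26740, 1.11280),
             b = c(3.28500, 8.84220, 0.313600, 129.424), c = 0.676000),
  MG = list(a = c(5.42040, 2.17350, 1.22690, 2.30730),
            b = c(2.82750, 79.2611, 0.380800, 7.19370), c = 0.858400),
  P  = list(a = c(6.43450, 4.17910, 1.78000, 1.49080),
            b = c(1.90670, 27.1570, 0.526000, 68.1645), c = 1.11490),
  S  = list(a = c(6.90530, 5.20340, 1.43790, 1.58630),
            b = c(1.46790, 22.2151, 0.253600, 56.1720), c = 0.866900),
  CL = list(a = c(11.4604, 7.19640, 6.25560, 1.64550),
            b = c(0.010400, 1.16620, 18.5194, 47.7784), c = -9.55740),
  K  = list(a = c(8.21860, 7.43980, 1.05190, 0.865900),
            b = c(12.7949, 0.774800, 213.187, 41.6841), c = 1.42280),
  CA = list(a = c(8.62660, 7.38730, 1.58990, 1.02110),
            b = c(10.4421, 0.659900, 85.7484, 178.437), c = 1.37510),
  FE = list(a = c(11.7695, 7.35730, 3.52220, 2.30450),
            b = c(4.76110, 0.307200, 15.3535, 76.8805), c = 1.03690)
)

.ff_env <- new.env(parent = emptyenv())

ff_table <- function() {
  if (is.null(.ff_env$extra)) .ff_env$extra <- list()
  c(.ff_env$extra, .ff_builtin)
}

#' Register a custom form factor
#'
#' @param element Element symbol.
#' @param a,b Gaussian coefficient vectors (equal length).
#' @param c Constant term.
#' @return Invisibly the stored coefficient list.
#' @export
register_form_factor <- function(element, a, b, c) {
  stopifnot(length(a) == length(b))
  key <- toupper(element)
  if (key == "NA") key <- "NA_"
  if (is.null(.ff_env$extra)) .ff_env$extra <- list()
  .ff_env$extra[[key]] <- list(a = a, b = b, c = c)
  invisible(.ff_env$extra[[key]])
}

ff_lookup <- function(elements) {
  tab <- ff_table()
  key <- toupper(elements)
  key[key == "NA"] <- "NA_"
  missing <- setdiff(unique(key), names(tab))
  if (length(missing)) {
    stop("no form factor coefficients for element(s): ",
         paste(sub("_$", "", missing), collapse = ", "), call. = FALSE)
  }
  key
}

#' Evaluate form factors
#'
#' @param element Character vector of element symbols.
#' @param s Numeric vector of `1/d` values (inverse Angstrom).
#' @return Matrix `length(s)` x `length(element)` of scattering factors.
#' @export
form_factor <- function(element, s) {
  tab <- ff_table()
  key <- ff_lookup(element)
  s2q <- s^2 / 4
  out <- vapply(key, function(k) {
    co <- tab[[k]]
    f <- rep(co$c, length(s))
    for (i in seq_along(co$a)) f <- f + co$a[i] * exp(-co$b[i] * s2q)
    f
  }, numeric(length(s)))
  matrix(out, nrow = length(s), dimnames = list(NULL, element))
}
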