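#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a pKa fit
#'
#' @param x A `pka_fit`.
#' @param ... Unused.
#' @return One row per parameter: `term`, `estimate`, plus bootstrap
#'   confidence bounds for the pKa.
#' @export
tidy.pka_fit <- function(x, ...) {
  tibble::tibble(
    term = c("pka", "base", "amp", "direction"),
    estimate = c(x$pka, x$base, x$amp, x$direction),
    conf.low = c(x$ci[1], NA, NA, NA),
    conf.high = c(x$ci[2], NA, NA, NA)
  )
}

#' @rdname tidy.pka_fit
#' @export
glance.pka_fit <- function(x, ...) {
  tibble::tibble(pka = x$pka, direction = x$direction, rss = x$rss,
                 nobs = x$n, converged = x$ok)
}

#' Tidy a bell-shaped pH-rate fit
#'
#' @param x A `bell_fit`.
#' @param ... Unused.
#' @return One row per parameter.
#' @export
tidy.bell_fit <- function(x, ...) {
  tibble::tibble(
    term = c("pka_rise", "pka_fall", "optimum", "vmax"),
    estimate = c(x$pka_rise, x$pka_fall, x$optimum, x$vmax)
  )
}

#' @rdname tidy.bell_fit
#' @export
glance.bell_fit <- function(x, ...) {
  tibble::tibble(pka_rise = x$pka_rise, pka_fall = x$pka_fall,
                 optimum = x$optimum, vmax = x$vmax, rss = x$rss,
                 nobs = x$n, converged = x$ok)
}
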