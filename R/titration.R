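#' Fit a single-pKa occupancy titration
#'
#' Least-squares fit of the Henderson-Hasselbalch logistic
#' `occ(pH) = base + amp / (1 + 10^(s (pH - pKa)))` with the direction
#' `s = +1` or `-1` selected by the lower residual sum — the data, not an
#' assumed orientation, decide which protonation state favors the shifted
#' conformer. Baseline and amplitude are bounded to \[0, 1\]. A bootstrap
#' percentile interval over point resampling (seeded) is attached. If the
#' sigmoid fits no better than a constant by AIC the result is flagged as a
#' fit failure rather than raising an error.
#'
#' @param t Tibble with columns `ph` and `occupancy` (or `y`); at least 4
#'   points.
#' @param n_boot Bootstrap resamples for the confidence interval
#'   (default 1000; 0 disables).
#' @param seed Bootstrap RNG seed.
#' @return A `pka_fit`: `pka`, `direction`, `base`, `amp`, `ci`,
#'   `residuals`, `ok`, plus the fitted curve function.
#' @export
fit_pka <- function(t, n_boot = 1000, seed = 1L) {
  ph <- t$ph
  y <- if ("occupancy" %in% names(t)) t$occupancy else t$y
  if (length(ph) < 4) stop("need at least 4 titration points", call. = FALSE)
  best <- fit_pka_core(ph, y)
  rss_const <- sum((y - mean(y))^2)
  n <- length(y)
  aicc <- function(rss, k) {
    n * log(max(rss, 1e-300) / n) + 2 * k + 2 * k * (k + 1) / max(n - k - 1, 1)
  }
  ok <- aicc(best$rss, 4) < aicc(rss_const, 2)
  ci <- c(NA_real_, NA_real_)
  if (ok && n_boot > 0) {
    set.seed(seed)
    boots <- replicate(n_boot, {
      idx <- sample.int(n, n, replace = TRUE)
      out <- tryCatch(fit_pka_core(ph[idx], y[idx], direction = best$direction),
                      error = function(e) NULL)
      if (is.null(out)) NA_real_ else out$pka
    })
    ci <- stats::quantile(boots, c(0.025, 0.975), na.rm = TRUE, names = FALSE)
    ci[1] <- min(ci[1], best$pka)
    ci[2] <- max(ci[2], best$pka)
  }
  structure(list(
    pka = best$pka, direction = best$direction, base = best$base,
    amp = best$amp, ci = ci, residuals = best$resid, rss = best$rss,
    ok = ok, n = n,
    curve = function(x) best$base + best$amp /
      (1 + 10^(best$direction * (x - best$pka))),
    data = tibble::tibble(ph = ph, occupancy = y)
  ), class = "pka_fit")
}

fit_pka_core <- function(ph, y, direction = NULL) {
  dirs <- if (is.null(direction)) c(1, -1) else direction
  span <- range(ph)
  fits <- lapply(dirs, function(s) {
    starts <- expand.grid(pka = seq(span[1], span[2], length.out = 3),
                          base = min(y), amp = diff(range(y)))
    best <- NULL
    for (r in seq_len(nrow(starts))) {
      fit <- tryCatch(minpack.lm::nlsLM(
        y ~ base + amp / (1 + 10^(s * (ph - pka))),
        start = list(base = starts$base[r], amp = max(starts$amp[r], 0.05),
                     pka = starts$pka[r]),
        lower = c(base = 0, amp = 0, pka = span[1] - 2),
        upper = c(base = 1, amp = 1, pka = span[2] + 2),
        control = minpack.lm::nls.lm.control(maxiter = 200)
      ), error = function(e) NULL)
      if (is.null(fit)) next
      rss <- sum(stats::resid(fit)^2)
      if (is.null(best) || rss < best$rss) {
        co <- stats::coef(fit)
        best <- list(pka = unname(co["pka"]), base = unname(co["base"]),
                     amp = unname(co["amp"]), rss = rss,
                     resid = stats::resid(fit), direction = s)
      }
    }
    best
  })
  fits <- fits[!vapply(fits, is.null, TRUE)]
  if (!length(fits)) stop("titration fit failed to converge", call. = FALSE)
  fits[[which.min(vapply(fits, function(f) f$rss, 0))]]
}

#' @export
print.pka_fit <- function(x, ...) {
  cat(sprintf(
    "<pka_fit> pKa = %.3f [%.3f, %.3f], direction %+d, base %.3f, amp %.3f%s\n",
    x$pka, x$ci[1], x$ci[2], x$direction, x$base, x$amp,
    if (x$ok) "" else "  (FIT FAILURE: no sigmoidal structure)"
  ))
  invisible(x)
}

#' Occupancy-ratio free energy difference
#'
#' Boltzmann relation between the populations of two conformers:
#' `Delta G = -R T ln(n2 / n1)` with `R = 8.314 J / (mol K)`, reported in
#' kJ/mol. Positive when the second conformer is less populated.
#'
#' @param n1,n2 Conformer occupancies in (0, 1].
#' @param temperature Temperature in K (default 298).
#' @return Free energy difference in kJ/mol.
#' @examples
#' delta_g(0.64, 0.36)  # ~1.43 kJ/mol
#' @export
delta_g <- function(n1, n2, temperature = 298) {
  if (n1 <= 0 || n2 <= 0) stop("occupancies must be positive", call. = FALSE)
  if (temperature <= 0) stop("temperature must be positive", call. = FALSE)
  R <- 8.314
  -R * temperature * log(n2 / n1) / 1000
}

#' Fit a bell-shaped pH-rate profile
#'
#' Double-ionization model
#' `v(pH) = vmax / ((1 + 10^(pKa_rise - pH)) (1 + 10^(pH - pKa_fall)))`:
#' activity requires one group deprotonated and another protonated. The
#' optimum is the analytic maximum of the fitted curve (the midpoint of the
#' two pKas for this parameterization).
#'
#' @param t Tibble with columns `ph` and `rate` (or `y`); at least 6
#'   points.
#' @return A `bell_fit`: `pka_rise`, `pka_fall`, `optimum`, `vmax`, `ok`,
#'   residuals and the fitted curve function.
#' @export
fit_ph_rate <- function(t) {
  ph <- t$ph
  y <- if ("rate" %in% names(t)) t$rate else t$y
  if (length(ph) < 6) stop("need at least 6 rate points", call. = FALSE)
  span <- range(ph)
  starts <- expand.grid(
    p1 = unname(stats::quantile(ph, c(0.2, 0.4))),
    p2 = unname(stats::quantile(ph, c(0.6, 0.8)))
  )
  best <- NULL
  for (r in seq_len(nrow(starts))) {
    fit <- tryCatch(minpack.lm::nlsLM(
      y ~ vmax / ((1 + 10^(p1 - ph)) * (1 + 10^(ph - p2))),
      start = list(vmax = max(y), p1 = starts$p1[r], p2 = starts$p2[r]),
      lower = c(vmax = 0, p1 = span[1] - 4, p2 = span[1] - 4),
      upper = c(vmax = Inf, p1 = span[2] + 4, p2 = span[2] + 4),
      control = minpack.lm::nls.lm.control(maxiter = 200)
    ), error = function(e) NULL)
    if (is.null(fit)) next
    rss <- sum(stats::resid(fit)^2)
    if (is.null(best) || rss < best$rss) {
      co <- stats::coef(fit)
      best <- list(vmax = unname(co["vmax"]), p1 = unname(co["p1"]),
                   p2 = unname(co["p2"]), rss = rss,
                   resid = stats::resid(fit))
    }
  }
  if (is.null(best)) stop("pH-rate fit failed to converge", call. = FALSE)
  n <- length(y)
  aicc <- function(rss, k) {
    n * log(max(rss, 1e-300) / n) + 2 * k + 2 * k * (k + 1) / max(n - k - 1, 1)
  }
  aic_fit <- aicc(best$rss, 4)
  aic_const <- aicc(sum((y - mean(y))^2), 2)
  structure(list(
    pka_rise = best$p1, pka_fall = best$p2,
    optimum = (best$p1 + best$p2) / 2, vmax = best$vmax,
    residuals = best$resid, rss = best$rss, ok = aic_fit < aic_const, n = n,
    curve = function(x) best$vmax /
      ((1 + 10^(best$p1 - x)) * (1 + 10^(x - best$p2))),
    data = tibble::tibble(ph = ph, rate = y)
  ), class = "bell_fit")
}

#' @export
print.bell_fit <- function(x, ...) {
  cat(sprintf(
    "<bell_fit> pKa_rise = %.3f, optimum = %.3f, pKa_fall = %.3f, vmax = %.4g%s\n",
    x$pka_rise, x$optimum, x$pka_fall, x$vmax,
    if (x$ok) "" else "  (FIT FAILURE)"
  ))
  invisible(x)
}

#' Absorbance slope to product rate
#'
#' Beer-Lambert conversion of a linear absorbance slope to a product
#' formation rate: `rate = slope / (epsilon * path) * 1e6` microM/s.
#'
#' @param slope Absorbance change per second.
#' @param epsilon Extinction coefficient (1/M/cm), default 1.33e4 (the
#'   320-nm coefficient of para-nitrophenyl formamide).
#' @param path Path length in cm (default 1).
#' @return Rate in microM/s.
#' @export
slope_to_rate <- function(slope, epsilon = 1.33e4, path = 1) {
  if (epsilon <= 0 || path <= 0) {
    stop("epsilon and path must be positive", call. = FALSE)
  }
  slope / (epsilon * path) * 1e6
}
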