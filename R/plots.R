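#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot a per-residue profile
#'
#' Bar chart of a `residue_profile` (IADDAT or B_diff values per residue).
#'
#' @param object A `residue_profile` tibble.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.residue_profile <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$resid, y = .data$value)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::labs(x = "Residue", y = "Value") +
    ggplot2::theme_minimal()
}

#' Plot a peak list
#'
#' Peak heights (sigma units) against distance to the nearest model atom,
#' colored by sign.
#'
#' @param object A `peak_list` tibble from [find_peaks()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.peak_list <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$dist,
                                       y = abs(.data$height_sigma),
                                       colour = .data$sign)) +
    ggplot2::geom_point() +
    ggplot2::scale_colour_manual(values = c("+" = "forestgreen", "-" = "firebrick")) +
    ggplot2::labs(x = "Distance to nearest atom (Å)",
                  y = "|Peak height| (σ)", colour = "Sign") +
    ggplot2::theme_minimal()
}

#' Plot a titration fit
#'
#' Observed occupancies with the fitted Henderson-Hasselbalch curve.
#'
#' @param object A `pka_fit`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.pka_fit <- function(object, ...) {
  grid <- tibble::tibble(ph = seq(min(object$data$ph), max(object$data$ph),
                                  length.out = 200))
  grid$occupancy <- object$curve(grid$ph)
  ggplot2::ggplot(object$data, ggplot2::aes(x = .data$ph, y = .data$occupancy)) +
    ggplot2::geom_point() +
    ggplot2::geom_line(data = grid, colour = "black") +
    ggplot2::labs(x = "pH", y = "Occupancy",
                  subtitle = sprintf("apparent pKa = %.2f", object$pka)) +
    ggplot2::theme_minimal()
}

#' Plot a bell-shaped pH-rate fit
#'
#' @param object A `bell_fit`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.bell_fit <- function(object, ...) {
  grid <- tibble::tibble(ph = seq(min(object$data$ph), max(object$data$ph),
                                  length.out = 200))
  grid$rate <- object$curve(grid$ph)
  ggplot2::ggplot(object$data, ggplot2::aes(x = .data$ph, y = .data$rate)) +
    ggplot2::geom_point() +
    ggplot2::geom_line(data = grid, colour = "black") +
    ggplot2::labs(x = "pH", y = "Rate (µM/s)") +
    ggplot2::theme_minimal()
}

#' Plot a Rosenfield difference matrix
#'
#' Heat map of the residue-binned mean `|Delta|` matrix.
#'
#' @param object A `rosenfield_matrix`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.rosenfield_matrix <- function(object, ...) {
  df <- expand.grid(i = seq_len(object$bins), j = seq_len(object$bins))
  df$value <- as.numeric(object$binned)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$i, y = .data$j,
                                   fill = .data$value)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_viridis_c() +
    ggplot2::labs(x = "Residue bin", y = "Residue bin",
                  fill = "|Δ| (Å²)") +
    ggplot2::theme_minimal()
}
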