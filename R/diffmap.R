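#' Scale one amplitude set onto another
#'
#' Least-squares scalar `k` minimizing `sum(|F_a| - k |F_b|)^2` over the
#' common Miller indices; only common indices are retained. Scaling is a
#' prerequisite of any isomorphous amplitude subtraction.
#'
#' @param ref_a Reference [reflection_set()].
#' @param ref_b Set to be scaled onto `ref_a`.
#' @param min_common Minimum number of common reflections (default 50).
#' @return List with `scaled` (ref_b restricted to common indices, scaled),
#'   `ref` (ref_a restricted likewise) and `k` (the scale factor).
#' @export
scale_amplitudes <- function(ref_a, ref_b, min_common = 50) {
  ta <- tibble::tibble(h = ref_a$tbl$h, k = ref_a$tbl$k, l = ref_a$tbl$l,
                       fa = amplitudes(ref_a))
  tb <- tibble::tibble(h = ref_b$tbl$h, k = ref_b$tbl$k, l = ref_b$tbl$l,
                       fb = amplitudes(ref_b),
                       sigb = if ("sigf" %in% names(ref_b$tbl))
                         ref_b$tbl$sigf else 0)
  m <- dplyr::inner_join(ta, tb, by = c("h", "k", "l"))
  if (nrow(m) < min_common) {
    stop("too few common reflections: ", nrow(m), " < ", min_common,
         call. = FALSE)
  }
  kscale <- sum(m$fa * m$fb) / sum(m$fb^2)
  scaled <- reflection_set(ref_b$cell, tibble::tibble(
    h = m$h, k = m$k, l = m$l, fobs = kscale * m$fb, sigf = kscale * m$sigb
  ), dmin = ref_b$dmin)
  ref <- reflection_set(ref_a$cell, tibble::tibble(
    h = m$h, k = m$k, l = m$l, fobs = m$fa
  ), dmin = ref_a$dmin)
  list(scaled = scaled, ref = ref, k = kscale)
}

#' Unweighted isomorphous difference map
#'
#' Scales `ref_off` onto `ref_on`, forms unweighted coefficients
#' `(|F_on| - k |F_off|) exp(i phi_calc)` with phases calculated from the
#' reference model, and synthesizes the map. The result carries its RMS
#' (`sigma`) for sigma-relative contouring; with `F(000)` omitted the map
#' mean is ~ 0. A weighting hook exists but defaults off.
#'
#' @param ref_on,ref_off Observed amplitude [reflection_set()]s.
#' @param phase_model A [xtal_structure()] providing calculated phases.
#' @param dmin Resolution cutoff for the synthesis.
#' @param weights Optional numeric vector (per common reflection) applied
#'   to the difference amplitudes; `NULL` (default) means unweighted.
#' @param phase_method `"fft"` (default) or `"direct"` phase calculation.
#' @param scale `"ls"` (default) least-squares scales `ref_off` onto
#'   `ref_on` first; `"none"` subtracts as-is (for pre-scaled sets, where
#'   order exchange negates the map exactly).
#' @return A [density_grid()].
#' @export
fo_minus_fo_map <- function(ref_on, ref_off, phase_model, dmin = NULL,
                            weights = NULL, phase_method = c("fft", "direct"),
                            scale = c("ls", "none")) {
  phase_method <- match.arg(phase_method)
  scale <- match.arg(scale)
  sc <- scale_amplitudes(ref_on, ref_off)
  if (scale == "none") sc$scaled$tbl$fobs <- sc$scaled$tbl$fobs / sc$k
  tbl <- dplyr::inner_join(
    tibble::tibble(h = sc$ref$tbl$h, k = sc$ref$tbl$k, l = sc$ref$tbl$l,
                   fon = sc$ref$tbl$fobs),
    tibble::tibble(h = sc$scaled$tbl$h, k = sc$scaled$tbl$k,
                   l = sc$scaled$tbl$l, foff = sc$scaled$tbl$fobs),
    by = c("h", "k", "l")
  )
  if (is.null(dmin)) dmin <- min(ref_on$dmin, ref_off$dmin)
  hkl <- as.matrix(tbl[, c("h", "k", "l")])
  keep <- d_spacing(ref_on$cell, hkl) >= dmin
  tbl <- tbl[keep, ]; hkl <- hkl[keep, , drop = FALSE]
  calc <- if (phase_method == "fft") {
    sf_fft(phase_model, dmin = dmin)
  } else {
    sf_direct(phase_model, hkl = hkl)
  }
  ph <- dplyr::inner_join(
    tbl,
    tibble::tibble(h = calc$tbl$h, k = calc$tbl$k, l = calc$tbl$l,
                   phase = Arg(calc$tbl$F)),
    by = c("h", "k", "l")
  )
  if (nrow(ph) < 0.95 * nrow(tbl)) {
    stop("phases missing for more than 5% of the common reflection set",
         call. = FALSE)
  }
  dF <- ph$fon - ph$foff
  if (!is.null(weights)) dF <- dF * weights
  coeff <- reflection_set(ref_on$cell, tibble::tibble(
    h = ph$h, k = ph$k, l = ph$l,
    F = complex(modulus = abs(dF), argument = ph$phase + ifelse(dF < 0, pi, 0))
  ), dmin = dmin)
  map_from_sf(coeff)
}

#' Find sigma-thresholded peaks in a difference map
#'
#' Local extrema of both signs with `|value| >= threshold_sigma * sigma`,
#' refined by per-axis three-point quadratic interpolation and filtered to
#' within `max_dist` of any model atom (minimum-image convention). Entries
#' are sorted by decreasing absolute height.
#'
#' @param map A [density_grid()] with sigma metadata.
#' @param threshold_sigma Contour threshold in sigma multiples.
#' @param model Optional [xtal_structure()] used for the distance filter
#'   and nearest-atom annotation.
#' @param max_dist Maximum distance to a model atom (Angstrom).
#' @return A tibble (class `peak_list`): fractional and cartesian
#'   positions, heights in e/A^3 and sigma units, sign, nearest atom and
#'   distance.
#' @export
find_peaks <- function(map, threshold_sigma = 3.2, model = NULL,
                       max_dist = 5) {
  v <- map$values
  dims <- map$dim
  if (map$sigma <= 0) return(empty_peak_list())
  thr <- threshold_sigma * map$sigma
  maxima <- local_extrema(v, decreasing = TRUE) & (v >= thr)
  minima <- local_extrema(v, decreasing = FALSE) & (v <= -thr)
  idx <- which(maxima | minima, arr.ind = TRUE)
  if (!nrow(idx)) return(empty_peak_list())
  rows <- lapply(seq_len(nrow(idx)), function(r) {
    i <- idx[r, ]
    offs <- vapply(1:3, function(ax) {
      im <- i; ip <- i
      im[ax] <- ((i[ax] - 2) %% dims[ax]) + 1
      ip[ax] <- (i[ax] %% dims[ax]) + 1
      y0 <- v[matrix(im, 1)]; y1 <- v[matrix(i, 1)]; y2 <- v[matrix(ip, 1)]
      den <- y0 - 2 * y1 + y2
      if (abs(den) < 1e-12) 0 else (y0 - y2) / (2 * den)
    }, numeric(1))
    frac <- ((i - 1 + offs) / dims) %% 1
    tibble::tibble(fx = frac[1], fy = frac[2], fz = frac[3],
                   height = v[matrix(i, 1)])
  })
  out <- dplyr::bind_rows(rows)
  cart <- frac_to_cart(map$cell, as.matrix(out[, c("fx", "fy", "fz")]))
  out$x <- cart[, 1]; out$y <- cart[, 2]; out$z <- cart[, 3]
  out$height_sigma <- out$height / map$sigma
  out$sign <- ifelse(out$height >= 0, "+", "-")
  if (!is.null(model)) {
    near <- nearest_atom(map$cell, as.matrix(out[, c("fx", "fy", "fz")]), model)
    out$nearest_atom <- near$label
    out$dist <- near$dist
    out <- dplyr::filter(out, .data$dist <= max_dist)
  } else {
    out$nearest_atom <- NA_character_
    out$dist <- NA_real_
  }
  out <- dplyr::arrange(out, dplyr::desc(abs(.data$height)))
  class(out) <- c("peak_list", class(out))
  out
}

empty_peak_list <- function() {
  out <- tibble::tibble(fx = double(), fy = double(), fz = double(),
                        height = double(), x = double(), y = double(),
                        z = double(), height_sigma = double(),
                        sign = character(), nearest_atom = character(),
                        dist = double())
  class(out) <- c("peak_list", class(out))
  out
}

# 26-neighbour local extremum detection with periodic wrap
local_extrema <- function(v, decreasing = TRUE) {
  dims <- dim(v)
  res <- array(TRUE, dims)
  shifts <- expand.grid(dx = -1:1, dy = -1:1, dz = -1:1)
  shifts <- shifts[!(shifts$dx == 0 & shifts$dy == 0 & shifts$dz == 0), ]
  roll <- function(a, s) {
    i1 <- ((seq_len(dims[1]) - 1 + s[1]) %% dims[1]) + 1
    i2 <- ((seq_len(dims[2]) - 1 + s[2]) %% dims[2]) + 1
    i3 <- ((seq_len(dims[3]) - 1 + s[3]) %% dims[3]) + 1
    a[i1, i2, i3, drop = FALSE]
  }
  for (r in seq_len(nrow(shifts))) {
    nb <- roll(v, as.numeric(shifts[r, ]))
    res <- res & if (decreasing) v >= nb else v <= nb
  }
  res
}

# nearest model atom (minimum-image in fractional space)
nearest_atom <- function(cell, frac_pts, model) {
  af <- as.matrix(model$atoms[, c("fx", "fy", "fz")])
  lab <- sprintf("%s%d:%s%s", model$atoms$resname, model$atoms$resid,
                 model$atoms$name,
                 ifelse(model$atoms$altloc == "", "",
                        paste0(".", model$atoms$altloc)))
  n <- nrow(frac_pts)
  label <- character(n); dist <- numeric(n)
  for (i in seq_len(n)) {
    d <- sweep(af, 2, frac_pts[i, ])
    d <- d - round(d)
    dc <- d %*% t(cell$orth)
    r <- sqrt(rowSums(dc^2))
    j <- which.min(r)
    label[i] <- lab[j]; dist[i] <- r[j]
  }
  list(label = label, dist = dist)
}

# grid points within radius of any atom of a selection (minimum image);
# returns linear indices
mask_indices <- function(map, model, radius) {
  dims <- map$dim
  cell <- map$cell
  af <- as.matrix(model$atoms[, c("fx", "fy", "fz")])
  frac_rownorm <- sqrt(rowSums(cell$frac^2))
  half <- ceiling(radius * frac_rownorm * dims)
  hit <- logical(prod(dims))
  for (i in seq_len(nrow(af))) {
    ctr_idx <- round(af[i, ] * dims)
    gx <- (ctr_idx[1] - half[1]):(ctr_idx[1] + half[1])
    gy <- (ctr_idx[2] - half[2]):(ctr_idx[2] + half[2])
    gz <- (ctr_idx[3] - half[3]):(ctr_idx[3] + half[3])
    pts <- cbind(
      rep.int(gx, length(gy) * length(gz)),
      rep.int(rep(gy, each = length(gx)), length(gz)),
      rep(gz, each = length(gx) * length(gy))
    )
    dfrac <- sweep(pts / matrix(dims, nrow(pts), 3, byrow = TRUE), 2, af[i, ])
    dc <- dfrac %*% t(cell$orth)
    near <- rowSums(dc^2) <= radius^2
    if (!any(near)) next
    w <- pts[near, , drop = FALSE]
    lin <- (w[, 1] %% dims[1]) + 1 +
      dims[1] * (w[, 2] %% dims[2]) +
      dims[1] * dims[2] * (w[, 3] %% dims[3])
    hit[lin] <- TRUE
  }
  which(hit)
}

#' Per-residue integrated absolute difference density (IADDAT)
#'
#' For each residue of the selection: the mean, over grid points within
#' `radius` of any selected atom of that residue, of the absolute map
#' value exceeding the noise threshold, `(|rho| - threshold)+`. The mean
#' (not the sum) decouples the score from residue size. Values are
#' non-negative and zero on sub-threshold maps.
#'
#' @param map A [density_grid()] with sigma metadata.
#' @param model A [xtal_structure()].
#' @param threshold_sigma Noise threshold in sigma multiples (default 3).
#' @param radius Integration radius around atoms (Angstrom, default 2.5).
#' @param selection `"all"` or `"mainchain"`.
#' @return Tibble (class `residue_profile`) with `chain`, `resid`, `value`.
#' @export
iaddat <- function(map, model, threshold_sigma = 3, radius = 2.5,
                   selection = "all") {
  sel <- if (identical(selection, "mainchain")) select_mainchain(model) else model
  if (nrow(sel$atoms) == 0) stop("empty selection", call. = FALSE)
  thr <- threshold_sigma * map$sigma
  resinfo <- dplyr::distinct(sel$atoms[, c("chain", "resid")])
  vals <- numeric(nrow(resinfo))
  for (r in seq_len(nrow(resinfo))) {
    sub <- filter_atoms(sel, .data$chain == resinfo$chain[r],
                        .data$resid == resinfo$resid[r])
    idx <- mask_indices(map, sub, radius)
    vals[r] <- if (length(idx)) {
      mean(pmax(abs(map$values[idx]) - thr, 0))
    } else 0
  }
  out <- tibble::tibble(chain = resinfo$chain, resid = resinfo$resid,
                        value = vals)
  class(out) <- c("residue_profile", class(out))
  out
}

#' Masked real-space map correlation
#'
#' Pearson correlation of two maps over the grid points within `radius` of
#' the selected atoms — e.g. the main-chain atoms of a residue range when
#' comparing an ensemble-derived difference map with an experimental one.
#'
#' @param map_a,map_b [density_grid()]s on identical grids.
#' @param model A [xtal_structure()] defining the mask.
#' @param selection `"all"` or `"mainchain"`.
#' @param radius Mask radius (Angstrom, default 2.0).
#' @return Correlation coefficient in \[-1, 1\].
#' @export
map_cc_masked <- function(map_a, map_b, model, selection = "mainchain",
                          radius = 2.0) {
  if (!all(map_a$dim == map_b$dim)) {
    stop("maps must share one grid", call. = FALSE)
  }
  sel <- if (identical(selection, "mainchain")) select_mainchain(model) else model
  idx <- mask_indices(map_a, sel, radius)
  if (length(idx) < 10) stop("mask covers fewer than 10 grid points", call. = FALSE)
  stats::cor(map_a$values[idx], map_b$values[idx])
}
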