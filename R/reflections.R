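#' Reflection sets
#'
#' A `reflection_set` holds Miller indices to a resolution cutoff together
#' with either calculated complex structure factors (column `F`) or observed
#' amplitudes with uncertainties (columns `fobs`, `sigf`) — or both. The
#' Friedel-unique hemisphere is stored; `F(000)` is always excluded.
#'
#' @param cell A [unit_cell()].
#' @param tbl Tibble with columns `h`, `k`, `l` and value columns.
#' @param dmin Resolution cutoff in Angstrom.
#' @return An object of class `reflection_set`.
#' @export
reflection_set <- function(cell, tbl, dmin) {
  tbl <- tibble::as_tibble(tbl)
  stopifnot(all(c("h", "k", "l") %in% names(tbl)))
  keep <- !(tbl$h == 0 & tbl$k == 0 & tbl$l == 0)
  tbl <- tbl[keep, ]
  if (anyDuplicated(tbl[, c("h", "k", "l")])) {
    stop("duplicate Miller indices in reflection set", call. = FALSE)
  }
  structure(list(cell = cell, dmin = dmin, tbl = tbl), class = "reflection_set")
}

#' @export
print.reflection_set <- function(x, ...) {
  cat(sprintf("<reflection_set> %d reflections to %.2f A (%s)\n",
              nrow(x$tbl), x$dmin,
              paste(setdiff(names(x$tbl), c("h", "k", "l")), collapse = ", ")))
  invisible(x)
}

#' @export
as_tibble.reflection_set <- function(x, ...) x$tbl

#' Friedel-unique Miller indices to a resolution limit
#'
#' Generates all indices with `d >= dmin`, keeping one member of each
#' Friedel pair (`h > 0`, or `h = 0, k > 0`, or `h = k = 0, l > 0`) and
#' excluding (0,0,0).
#'
#' @param cell A [unit_cell()].
#' @param dmin Resolution cutoff (Angstrom), > 0.
#' @return Integer matrix with columns h, k, l.
#' @export
miller_indices <- function(cell, dmin) {
  stopifnot(dmin > 0)
  hmax <- ceiling(cell$a / dmin) + 1
  kmax <- ceiling(cell$b / dmin) + 1
  lmax <- ceiling(cell$c / dmin) + 1
  grid <- expand.grid(h = -hmax:hmax, k = -kmax:kmax, l = 0:lmax)
  hkl <- as.matrix(grid)
  uniq <- hkl[, 3] > 0 |
    (hkl[, 3] == 0 & hkl[, 1] > 0) |
    (hkl[, 3] == 0 & hkl[, 1] == 0 & hkl[, 2] > 0)
  hkl <- hkl[uniq, , drop = FALSE]
  d <- d_spacing(cell, hkl)
  hkl <- hkl[d >= dmin, , drop = FALSE]
  hkl[order(hkl[, 1], hkl[, 2], hkl[, 3]), , drop = FALSE]
}

#' Amplitudes of a reflection set
#' @param r A [reflection_set()].
#' @return Numeric vector: `Mod(F)` if complex values present, else `fobs`.
#' @export
amplitudes <- function(r) {
  if ("F" %in% names(r$tbl)) Mod(r$tbl$F) else r$tbl$fobs
}

#' Write reflections as a TSV table
#'
#' Columns `h k l F sigF [phase_deg]`: complex sets write amplitude and
#' phase; amplitude sets write `fobs`/`sigf`.
#'
#' @param r A [reflection_set()].
#' @param path Output path.
#' @return Invisibly `path`.
#' @export
write_reflections <- function(r, path) {
  tbl <- r$tbl
  if ("F" %in% names(tbl)) {
    out <- tibble::tibble(
      h = tbl$h, k = tbl$k, l = tbl$l,
      F = sprintf("%.6f", Mod(tbl$F)),
      sigF = sprintf("%.6f", if ("sigf" %in% names(tbl)) tbl$sigf else 0),
      phase_deg = sprintf("%.4f", Arg(tbl$F) * 180 / pi)
    )
  } else {
    out <- tibble::tibble(
      h = tbl$h, k = tbl$k, l = tbl$l,
      F = sprintf("%.6f", tbl$fobs),
      sigF = sprintf("%.6f", if ("sigf" %in% names(tbl)) tbl$sigf else 0)
    )
  }
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read reflections from a TSV table
#'
#' @param path Input path with header `h k l F sigF [phase_deg]`.
#' @param cell The [unit_cell()] the indices refer to.
#' @return A [reflection_set()]; complex `F` reconstructed when a phase
#'   column is present, else amplitude columns `fobs`/`sigf`.
#' @export
read_reflections <- function(path, cell) {
  tbl <- utils::read.table(path, header = TRUE, sep = "\t")
  dmin <- min(d_spacing(cell, as.matrix(tbl[, c("h", "k", "l")])))
  if ("phase_deg" %in% names(tbl)) {
    out <- tibble::tibble(
      h = as.integer(tbl$h), k = as.integer(tbl$k), l = as.integer(tbl$l),
      F = complex(modulus = tbl$F, argument = tbl$phase_deg * pi / 180),
      sigf = tbl$sigF
    )
  } else {
    out <- tibble::tibble(
      h = as.integer(tbl$h), k = as.integer(tbl$k), l = as.integer(tbl$l),
      fobs = tbl$F, sigf = tbl$sigF
    )
  }
  reflection_set(cell, out, dmin)
}

#' Read an mmCIF structure-factor block
#'
#' Supports `_refln` loops carrying `index_h/k/l` with either measured
#' amplitudes (`F_meas_au` + `F_meas_sigma_au`) or calculated values
#' (`F_calc_au`/`F_calc` + `phase_calc`).
#'
#' @param path mmCIF file path.
#' @param cell The [unit_cell()] the indices refer to.
#' @return A [reflection_set()].
#' @export
read_mmcif_sf <- function(path, cell) {
  lines <- readLines(path, warn = FALSE)
  tbl <- cif_loop(lines, "_refln.")
  if (is.null(tbl)) stop("no _refln loop found in ", path, call. = FALSE)
  h <- as.integer(tbl$index_h); k <- as.integer(tbl$index_k)
  l <- as.integer(tbl$index_l)
  dmin <- min(d_spacing(cell, cbind(h, k, l)))
  if ("F_meas_au" %in% names(tbl)) {
    out <- tibble::tibble(
      h = h, k = k, l = l, fobs = as.numeric(tbl$F_meas_au),
      sigf = if ("F_meas_sigma_au" %in% names(tbl))
        as.numeric(tbl$F_meas_sigma_au) else 0
    )
  } else {
    fc <- if ("F_calc_au" %in% names(tbl)) tbl$F_calc_au else tbl$F_calc
    if (is.null(fc) || !"phase_calc" %in% names(tbl)) {
      stop("_refln loop has neither measured nor calculated amplitudes",
           call. = FALSE)
    }
    out <- tibble::tibble(
      h = h, k = k, l = l,
      F = complex(modulus = as.numeric(fc),
                  argument = as.numeric(tbl$phase_calc) * pi / 180)
    )
  }
  reflection_set(cell, out, dmin)
}
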