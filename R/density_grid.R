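#' Real-space density grid
#'
#' A scalar field sampled on a cell-commensurate grid (0-based indices,
#' fractional coordinates in half-open `[0, 1)`), with optional sigma
#' metadata (RMS over the full grid) used for sigma-relative contouring.
#'
#' @param cell A [unit_cell()].
#' @param values 3D numeric array; first index varies fastest along a.
#' @param sigma Optional RMS value; computed from `values` when `NULL`.
#' @return Object of class `density_grid`.
#' @export
density_grid <- function(cell, values, sigma = NULL) {
  stopifnot(inherits(cell, "unit_cell"), length(dim(values)) == 3)
  if (is.null(sigma)) sigma <- sqrt(mean(values^2))
  structure(list(cell = cell, dim = dim(values), values = values,
                 sigma = sigma), class = "density_grid")
}

#' @export
print.density_grid <- function(x, ...) {
  cat(sprintf("<density_grid> %d x %d x %d, sigma = %.4g e/A^3\n",
              x$dim[1], x$dim[2], x$dim[3], x$sigma))
  invisible(x)
}

# smallest 2,3,5-smooth integer >= n (FFT-friendly grid dimensions)
smooth_grid_size <- function(n) {
  n <- as.integer(ceiling(n))
  repeat {
    m <- n
    for (p in c(2L, 3L, 5L)) while (m %% p == 0L) m <- m %/% p
    if (m == 1L) return(n)
    n <- n + 1L
  }
}

#' Grid dimensions for a resolution cutoff
#'
#' Default rule: grid spacing at most `dmin / 3` along each axis, rounded
#' up to FFT-friendly (2,3,5-smooth) sizes.
#'
#' @param cell A [unit_cell()].
#' @param dmin Resolution (Angstrom).
#' @param rule Spacing rule as a fraction of `dmin` (default 1/3).
#' @return Integer vector of three grid dimensions.
#' @export
grid_dim_for <- function(cell, dmin, rule = 1 / 3) {
  stopifnot(dmin > 0, rule > 0)
  spacing <- dmin * rule
  vapply(c(cell$a, cell$b, cell$c),
         function(len) smooth_grid_size(len / spacing), integer(1))
}

# fractional coordinates of all grid points (n x 3), index varying
# fastest along the first axis to match R array storage order
grid_frac_coords <- function(dim) {
  cbind(
    rep.int((seq_len(dim[1]) - 1) / dim[1], dim[2] * dim[3]),
    rep.int(rep((seq_len(dim[2]) - 1) / dim[2], each = dim[1]), dim[3]),
    rep((seq_len(dim[3]) - 1) / dim[3], each = dim[1] * dim[2])
  )
}

#' Write a density grid as a CCP4/MRC map (mode 2)
#'
#' @param g A [density_grid()].
#' @param path Output path.
#' @return Invisibly `path`.
#' @export
write_ccp4 <- function(g, path) {
  con <- file(path, "wb")
  on.exit(close(con))
  d <- g$dim
  wi <- function(x) writeBin(as.integer(x), con, size = 4, endian = "little")
  wf <- function(x) writeBin(as.numeric(x), con, size = 4, endian = "little")
  wi(d)                       # NC NR NS
  wi(2)                       # MODE 2: float32
  wi(c(0, 0, 0))              # start
  wi(d)                       # sampling NX NY NZ
  wf(c(g$cell$a, g$cell$b, g$cell$c, g$cell$alpha, g$cell$beta, g$cell$gamma))
  wi(c(1, 2, 3))              # axis order
  wf(c(min(g$values), max(g$values), mean(g$values)))
  wi(1)                       # ISPG
  wi(0)                       # NSYMBT
  wi(rep(0, 28))              # extra (words 25-52)
  writeBin(charToRaw("MAP "), con)
  writeBin(as.raw(c(0x44, 0x41, 0x00, 0x00)), con)  # little-endian stamp
  wf(g$sigma)                 # ARMS
  wi(0)                       # NLABL
  writeBin(raw(200 * 4), con) # labels
  wf(as.numeric(g$values))
  invisible(path)
}

#' Read a CCP4/MRC map (mode 2, axis order 1,2,3)
#'
#' @param path Map file path.
#' @return A [density_grid()].
#' @export
read_ccp4 <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  ri <- function(n) readBin(con, "integer", n, size = 4, endian = "little")
  rf <- function(n) readBin(con, "numeric", n, size = 4, endian = "little")
  d <- ri(3)
  mode <- ri(1)
  if (mode != 2) stop("only mode-2 (float) maps are supported", call. = FALSE)
  ri(3); samp <- ri(3)
  cellv <- rf(6)
  axes <- ri(3)
  if (!all(axes == c(1, 2, 3))) {
    stop("only axis order 1,2,3 is supported", call. = FALSE)
  }
  rf(3); ri(1)
  nsymbt <- ri(1)
  ri(28); readBin(con, "raw", 8)
  sigma <- rf(1)
  ri(1); readBin(con, "raw", 200 * 4)
  if (nsymbt > 0) readBin(con, "raw", nsymbt)
  vals <- rf(prod(d))
  cell <- unit_cell(cellv[1], cellv[2], cellv[3], cellv[4], cellv[5], cellv[6])
  density_grid(cell, array(vals, dim = d), sigma = sigma)
}
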