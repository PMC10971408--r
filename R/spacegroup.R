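#' Space group
#'
#' Minimal space-group support: symmetry operators in fractional coordinates
#' as (rotation, translation) pairs. `P 1` and `C 2` (plus `P 2` and
#' `P 21`) are built in, which covers triclinic toy systems and the
#' monoclinic C-centred setting used throughout.
#'
#' @param symbol Space-group symbol, e.g. `"P1"` or `"C2"`. Spaces are
#'   ignored.
#' @return An object of class `spacegroup` with fields `symbol` and `ops`,
#'   a list of `list(R = 3x3 matrix, t = length-3 vector)` operators in
#'   fractional coordinates.
#' @examples
#' spacegroup("C2")$symbol
#' length(spacegroup("C2")$ops)
#' @export
spacegroup <- function(symbol = "P1") {
  key <- toupper(gsub("[ ]", "", symbol))
  I3 <- diag(3)
  rot2y <- diag(c(-1, 1, -1))  # two-fold along b
  ops <- switch(key,
    "P1" = list(list(R = I3, t = c(0, 0, 0))),
    "P2" = list(
      list(R = I3, t = c(0, 0, 0)),
      list(R = rot2y, t = c(0, 0, 0))
    ),
    "P21" = list(
      list(R = I3, t = c(0, 0, 0)),
      list(R = rot2y, t = c(0, 0.5, 0))
    ),
    "C2" = list(
      list(R = I3, t = c(0, 0, 0)),
      list(R = rot2y, t = c(0, 0, 0)),
      list(R = I3, t = c(0.5, 0.5, 0)),
      list(R = rot2y, t = c(0.5, 0.5, 0))
    ),
    stop("unsupported space group: ", symbol, call. = FALSE)
  )
  structure(list(symbol = key, ops = ops), class = "spacegroup")
}

#' @export
print.spacegroup <- function(x, ...) {
  cat(sprintf("<spacegroup> %s (%d operators)\n", x$symbol, length(x$ops)))
  invisible(x)
}

#' Number of symmetry operators
#' @param sg A [spacegroup()].
#' @return Integer operator count.
#' @export
n_ops <- function(sg) length(sg$ops)

# verify closure of the operator set modulo lattice translations
sg_is_closed <- function(sg) {
  ops <- sg$ops
  key <- function(R, t) paste(c(round(R), round(t %% 1, 6)), collapse = ",")
  have <- vapply(ops, function(o) key(o$R, o$t), "")
  for (a in ops) for (b in ops) {
    R <- a$R %*% b$R
    t <- (a$R %*% b$t + a$t) %% 1
    if (!key(R, t) %in% have) return(FALSE)
  }
  TRUE
}
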