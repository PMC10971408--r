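#' Ensemble-averaged structure factors from supercell frames
#'
#' The lattice-and-time averaging step: every atom of every frame is folded
#' back into one crystallographic unit cell (supercell fraction times dims,
#' modulo 1) and the unit-cell structure factor of each frame is computed
#' by exact direct summation with per-atom B = 0 — the disorder is carried
#' by the ensemble itself, not by a Debye-Waller model. The complex
#' structure factors are averaged over frames (equivalent to averaging the
#' density), mirroring what x-ray diffraction measures from a crystal.
#'
#' @param frames A `supercell_frames` object ([make_ensemble()] or
#'   [read_ensemble_pdb()]).
#' @param selection Component filter: `"all"`, `"protein"`, `"water"`, or
#'   an ion element symbol (e.g. `"MG"`).
#' @param dmin Resolution cutoff (Angstrom).
#' @return A [reflection_set()] on the unit cell with complex column `F`.
#' @export
sf_ensemble <- function(frames, selection = "all", dmin = 2.0) {
  stopifnot(inherits(frames, "supercell_frames"), dmin > 0)
  base <- frames$base
  dims <- frames$dims
  scl <- base$cell
  ucell <- unit_cell(scl$a / dims[1], scl$b / dims[2], scl$c / dims[3],
                     scl$alpha, scl$beta, scl$gamma)
  keep <- component_mask(base$atoms, selection)
  if (!any(keep)) stop("empty selection: ", selection, call. = FALSE)
  elements <- base$atoms$element[keep]
  hkl <- miller_indices(ucell, dmin)
  acc <- complex(nrow(hkl))
  for (f in seq_along(frames$frames)) {
    fr <- frames$frames[[f]][keep, , drop = FALSE]
    folded <- sweep(fr, 2, dims, "*") %% 1
    acc <- acc + sf_sum(ucell, hkl, folded, elements,
                        occ = rep(1, nrow(folded)), u6 = NULL)
  }
  Fv <- acc / length(frames$frames)
  # normalize to one unit cell: the fold summed all supercell copies
  Fv <- Fv / prod(dims)
  reflection_set(ucell, tibble::tibble(h = hkl[, 1], k = hkl[, 2],
                                       l = hkl[, 3], F = Fv),
                 dmin = min(d_spacing(ucell, hkl)))
}

component_mask <- function(atoms, selection) {
  switch(tolower(selection),
    all = rep(TRUE, nrow(atoms)),
    protein = atoms$record == "ATOM",
    water = atoms$resname %in% c("HOH", "WAT"),
    adduct = atoms$resname == "ADT",
    toupper(atoms$element) == toupper(selection) & atoms$record == "HETATM" &
      !atoms$resname %in% c("HOH", "WAT", "ADT")
  )
}
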