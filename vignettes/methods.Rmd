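---
title: "Methods: ensemble structure factors and difference-map analytics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: ensemble structure factors and difference-map analytics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mdmx)
```

## The problem

Enzymes in crystals are ensembles. A refined crystal structure encodes that
heterogeneity implicitly: alternate conformers with partial occupancies,
and atomic displacement parameters (ADPs) describing Gaussian disorder
about each position. A crystalline simulation, or any explicit ensemble
model, encodes the same physics explicitly: many copies of the molecule,
each in one definite state. Diffraction averages over both space (every
unit cell in the crystal) and time (the exposure), so the two descriptions
must agree in reciprocal space if they describe the same crystal. `mdmx`
makes that correspondence computable, and builds the difference-map
analytics used to localize state changes between two experimental (or two
computed) datasets.

## Supercell construction with occupancy-consistent sampling

A supercell of `N1 x N2 x N3` unit cells contains
`N = N1 N2 N3 x n_ops` copies of the asymmetric unit. Each *conformer
site* (a group of atoms sharing an altloc label and one grouped occupancy
over a residue range) is resolved to a single conformer per copy.

Two assignment methods are provided:

* **quota** (default): each conformer receives its largest-remainder share
  of `N x occ` copies. The counts are dealt round-robin across the
  symmetry-operator strata, so each crystallographic environment realizes
  the occupancies as closely as integer counts allow, and placement within
  a stratum is uniformly random. The rationale is that at crystallographic
  copy counts (32 in a 2x2x2 monoclinic C-centred supercell) i.i.d.
  sampling routinely misses the refined occupancies by several copies,
  whereas the population of the simulated crystal must be *consistent*
  with refinement for the ensemble-vs-data comparison to be meaningful.
* **multinomial**: i.i.d. per copy, converging to the occupancies only as
  `N` grows. Useful for statistical null experiments.

The stratified deal has one documented consequence: when a conformer's
global count does not divide evenly among the operator strata (e.g. 27
reactive copies over 4 strata), strata differ by one copy and the
lattice-averaged structure factor deviates from the occupancy-weighted
single model at order `1/N`. When counts divide evenly (20/12 over 4
strata), the equivalence is exact to machine precision, and the test suite
pins it at `1e-6` relative.

A covalent adduct is assigned in a **second, conditional round**: only
copies whose nucleophile realized the reactive conformer are eligible, and
`round(n_reactive x p)` of them (quota) receive the adduct. This encodes
the chemical constraint that a modification can only exist on the
conformer it is bonded to; the marginal adduct frequency is then
`p x occ_reactive`, matching a refined adduct occupancy when
`p = occ_adduct / occ_reactive`.

Ion bookkeeping converts buffer concentrations to integer counts,
`N = round(C V N_A)` over a stated solvent volume, with a configurable
ceiling mode. With the worked solvent volume of `1.0379e-21` L and 125 mM
Mg²⁺ this gives 78 ions; published totals for monovalent species in
comparable workflows are not always reproducible from stated
concentrations alone (neutralization ions are a separate, explicitly
labeled budget), so the rounding rule is exposed rather than guessed.

## Structure factors

`sf_direct()` is the oracle: exact summation of
`occ x f(s) x DW x exp(2 pi i h.(Rx + t))` over atoms and operators, with
International-Tables-style 4-Gaussian form factors (`f(0)` equals the
electron count to 0.1 e⁻) and the anisotropic Debye-Waller factor
`exp(-2 pi^2 s' U s)` on the cartesian reciprocal vector. Hydrogens, when
present, are summed with their own form factor — matching refined models
that carry riding hydrogens without special-casing them.

`sf_fft()` samples each atom as the real-space Gaussian mixture dual to
its form factor — term `i` has covariance `U + (b_i / 8 pi^2) I` — on a
grid with spacing at most `d_min/3` (2,3,5-smooth dimensions), truncated
at 4.5 sigma, then Fourier-analyses the grid. These defaults keep the
amplitude-weighted disagreement with the oracle well under 1% for ADPs in
the 10–25 Å² range typical of room-temperature structures; the sharp
constant term of the form factor is carried by the ADP alone, so the FFT
path assumes non-zero ADPs and refuses pathological B = 0 models.

`sf_ensemble()` implements the time-and-lattice average: per frame, every
atom is folded into one unit cell (`supercell fraction x dims mod 1`) and
summed with per-atom B = 0 and occupancy 1 — the ensemble spread *is* the
disorder model — then the complex `F` is averaged over frames (equivalent
to averaging density). Per-component selections (protein, water, adduct,
ion species) restrict the atom set before summation and are exactly
additive.

No bulk-solvent model is applied and `F(000)` is always omitted: all
downstream use is difference maps, where a flat solvent term cancels.

## Difference maps

Isomorphous difference maps use unweighted coefficients
`(|F_on| - k |F_off|) exp(i phi_calc)`: a least-squares scale
`k = Σ|F_on||F_off| / Σ|F_off|²` on the common indices, phases from a
reference model, no weighting (a weighting hook exists but defaults off).
Because `k(a,b) != 1/k(b,a)`, exact antisymmetry under order exchange
holds for pre-scaled inputs (`scale = "none"`); with least-squares scaling
the asymmetry is bounded by the scale mismatch and tested at tolerance.
The map sigma is the RMS over the whole unit-cell grid, the conventional
normalization behind "contoured at 3σ".

Peaks are 26-neighbour local extrema of both signs above a σ-relative
threshold, refined by per-axis 3-point quadratic interpolation (ties
broken by grid order, for determinism), and filtered to within a distance
cutoff of the model (minimum-image). IADDAT integrates
`(|rho| - threshold)+` over grid points within a radius of each residue's
atoms and reports the **mean** per residue, decoupling the score from
residue size; defaults are threshold 3σ and radius 2.5 Å, declared rather
than inherited since the field's parameterizations vary. Masked map
correlations are plain Pearson correlations over grid points within 2.0 Å
of the selected atoms (a hard mask; tight enough to isolate main-chain
signal for a residue range).

## ADP analytics

`residue_bdiff()` averages `B_on - B_off` over matched main-chain atoms
per residue, using the altloc-A conformer when alternates exist (the
convention of taking the most-occupied conformer). `principal_axes()`
eigen-decomposes the cartesian U tensor with eigenvalues sorted descending
and a deterministic sign convention. `peak_axis_alignment()` reports the
absolute cosine between a paired-peak displacement vector and the major
axis — near 1 when an apparent atomic shift runs along the preferred
direction of motion. `rosenfield()` projects both tensors of every atom
pair on their interatomic direction; the difference matrix is
antisymmetric by construction and vanishes identically for rigid-body
translation. The rigid-body "pass" criterion (binned mean |Δ| < 0.001 Å²)
is a declared operationalization: the underlying qualitative claim has no
standard numeric threshold, so this one is configurable and stated.

## Titrations and free energies

The Henderson-Hasselbalch fit is
`occ(pH) = base + amp / (1 + 10^{s(pH - pKa)})` with the direction
`s = ±1` **fitted**, not assumed: the canonical equation orients the ratio
one way, but occupancy data can run in either direction depending on which
state is labeled "shifted", and hard-coding the sign silently produces
nonsense pKas on the other orientation. Baseline and amplitude are bounded
to [0, 1] (crystallographic occupancies rarely span the full range).
Uncertainty comes from a seeded 1000-resample bootstrap (percentile
interval), appropriate at the ~6–9 point scale of typical pH series, where
asymptotic standard errors are optimistic. A sigmoid that fits no better
than a constant by small-sample AIC is returned as a flagged fit failure
rather than an error.

The pH-rate profile uses the double-ionization bell
`v = vmax / ((1 + 10^{pKa1 - pH})(1 + 10^{pH - pKa2})})`. Its analytic
maximum lies at the midpoint of the two pKas; empirical "dose-response"
fits in the literature sometimes report an optimum that is not that
midpoint, which simply means a different parameterization was fitted — the
reported optimum here is always the analytic maximum of this model.

`delta_g()` evaluates `-RT ln(n2/n1)` in kJ/mol. At occupancies 0.64/0.36
and 298 K this is 1.43 kJ/mol; note that published figures computed from
nearby but unprinted occupancies (e.g. 0.65/0.35 gives 1.53) will differ,
so the function documents the formula and leaves reconciliation to the
caller.

## The synthetic toy crystal

`make_toy_pair()` generates a deterministic two-state system designed to
carry every statistical feature the analysis consumes, at a size where the
full pipeline runs in seconds: a 25 x 20 x 18 Å P1 cell (a monoclinic C2
variant exercises the symmetry paths) with 10 pseudo-residues of 4
main-chain atoms plus one side-chain atom. The 30 s state differs from the
resting state only by: a 3-atom covalent adduct at occupancy 0.53 bonded
to the reactive (0.85) nucleophile conformer, loop occupancies
redistributed 0.64 → 0.39, a modest ADP increase at the active site, and a
gated water at 0.64 placed within steric-clash distance (< 2.2 Å) of the
closed loop conformer — so the water's difference-density signature can
only appear when the loop opens, reproducing the gating logic of the real
system. Observed amplitudes add multiplicative Gaussian noise
(`sd = noise_frac x |F|`), sufficient for σ-contour testing.

What the toy does **not** emulate: real protein topology and chemistry,
solvent beyond the single gated water, bulk-solvent scattering,
resolution-dependent error models, radiation damage, or non-isomorphism.
Passing tests therefore demonstrate the correctness of the computational
machinery on data with the assumed statistical structure, not performance
on real diffraction data.

## Problem sizes and numerical choices

The test and acceptance runs use the toy systems at 1.5–2.5 Å resolution
(2–6 thousand reflections, 60–70 atoms per cell; 32-copy supercells;
ensembles of 1–10 frames; 150–200 seeds for recovery simulations; 4000
frames for the displacement-covariance check), chosen so the entire suite
completes in about a minute while every property is tested at its stated
tolerance. Degenerate inputs are errors, not silent defaults: cells with
non-positive volume, amplitude sets without phases, masks under 10 grid
points, occupancy groups that sum below 0.99 with no declared absent
state, FFT sampling of B = 0 atoms.

## Known limitations

- Space-group support is deliberately minimal (P1, P2, P2₁, C2): the
  monoclinic C-centred case covers the target analysis; general symmetry
  would need a full operator library.
- The mmCIF reader covers the documented subset used for model exchange,
  not the full specification.
- Rosenfield matrices treat isotropic atoms by the isotropic-tensor
  fallback with a warning; TLS-style libration fixtures are exact only to
  first order in the libration angle.
- Difference maps are unweighted by design; σ-A style weighting is out of
  scope.
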