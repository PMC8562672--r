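---
title: "Quantifying collagen glycation from SAXS/WAXS: models, parameters, and numerical choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying collagen glycation from SAXS/WAXS}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(glycofibril)
```

This vignette is the package's own account of the science it implements:
the structural model of the collagen fibril, the phase-retrieval scheme
that extracts the glycation density, the kinetics model that predicts
glycation over years, and — importantly — the places where the design was
genuinely open and what we chose.

## The staggered fibril and its two-level density

A collagen fibril packs ~306 nm triple-helix molecules with an axial
stagger of one D-period (d_M ≈ 65.5 nm) and a lateral spacing d_E ≈ 1.5 nm.
Because the molecule length is not an integer multiple of d_M, each period
splits into an *overlap* band (five molecule fractions, width σ·d_M) and a
*gap* band (four fractions plus a gap, width (1 − σ)·d_M). Projected onto
the fibril axis the electron density is, to first approximation, two-level,
and its Fourier moduli are |F_n| ∝ |sin(πnσ)|/(πn). Two consequences we
rely on throughout:

* the overlap fraction σ is measurable from relative Bragg amplitudes
  alone (`fit_two_level_model()`); σ and 1 − σ give identical moduli, so we
  resolve the ambiguity to σ ≤ 0.5 by convention;
* the zero-order reflection is not measured, so only density *differences*
  relative to the unknown mean are accessible; absolute contrasts enter the
  pipeline as tabulated observables, never from amplitudes.

The in-plane unit cell (five molecules) is modelled as k·d_E² with k
calibrated once against the 21.9 nm² swollen-cell area at the reference
spacing d_E = 1.514 nm; the native cell is 26% smaller (17.4 nm²). We did
not attempt to reconstruct the full parallelogram geometry of the packing —
the quadratic surrogate preserves the only quantitative anchors (21.9,
17.4 nm², factor 1.26) without inventing lattice angles, and it is exact
for any similarity-scaling of the cell. From the native free-area fraction
w_nat = 0.255 shared by five molecules, the per-molecule free area is
0.051 × 17.4 nm² = 89 Å² (`psa_nat_estimate()`), the reference scale
against which sugar polar surface areas are compared.

## Peak indexing: windows, background, and why they look the way they do

Meridional peaks sit on a diffuse background orders of magnitude larger
than the high-order reflections, falling roughly as 1/q². Three choices in
`index_meridional_peaks()` deserve explanation:

* **Sequential centre location.** A 1% error in the period guess displaces
  the predicted 15th-order position by ~15% of the peak spacing; windows
  centred on a fixed guess lose high orders entirely. We therefore index
  order by order, refitting the period after each peak so the prediction
  tracks the data. Centres come from a centre-of-mass above half maximum,
  which is robust against the flat, noise-dominated peak tops that defeat
  a 3-point parabola.
* **Local background basis (1, q, 1/q²).** A straight line through the
  flanking windows over-subtracts the low orders because the diffuse term
  is strongly curved there; adding the 1/q² basis function removes a global
  diffuse term exactly while remaining a small, local, linear least-squares
  fit. Flanks sit 0.25–0.4 peak spacings from the centre, far enough that
  the peak's own tails (≲0.3% of its area) do not bias the fit.
* **Fixed integration window (±0.25 spacings ≈ ±3 instrumental widths).**
  Truncation then captures the same fraction of every peak's area, so the
  bias is common-mode and cancels in relative amplitudes — and only
  relative amplitudes are used downstream (the phasing rescales to the
  first native order; the σ fit is scale-free). On noiseless synthetic
  profiles the relative moduli are accurate to ~0.5%; this, not machine
  precision, is the realistic accuracy of any window-integration estimator
  on curved background, and tests assert it at that level.

## Two-stage phasing

`phase_refine()` implements plain alternating projections
(error-reduction): a modulus projector that replaces |F_n| at measured
orders (default 1..15) with the targets while keeping phases, and a
positivity projector that clips the density at zero. No feedback parameter
is used — constraint imposition is kept as simple as the scheme it
implements. Unmeasured orders, including order 0, are left entirely to the
positivity constraint.

Stage 1 phases ρ_ini and ρ_fin jointly from a step-function start (1 on
half the period, 0 elsewhere — the minimal unbiased prior), replacing both
trials with their average for the first 90% of 200 iterations, then letting
them evolve independently. Stage 2 phases the difference density for 500
iterations with targets |ΔF_n| = ||F_fin,n| − |F_ini,n||; difference
amplitudes may be negative, and since moduli cannot be, the sign is
discarded and absorbed into the retrieved phase. Seven outer cycles repeat
the pair, reseeding stage 1 with the previous native solution and
native + glycation estimate.

Numerical choices:

* **Rescaling.** Both moduli sets are divided by the native order-1
  modulus. This matters: the step start has order-1 modulus 1/π, and if the
  measured moduli are small relative to it, the iterate never goes
  negative, positivity never acts, and the iteration stalls at the start
  (we observed recovery correlations near zero without the rescaling and
  ~0.95 with it).
* **Grid.** 1930 points per period by default, shared with the residue-map
  raster; results are grid-stable (tested at 960 and 3860).
* **Divergence guard and monotonicity.** The modulus residual is tracked
  every iteration; growth to 10× its running minimum aborts with a
  diagnostic, and non-monotone behaviour over the last 10% of a stage
  raises a warning (alternating projections need not be globally monotone).
* **Determinism.** The algorithm has no random element; identical inputs
  give bit-identical outputs.

Phase retrieval from moduli alone cannot distinguish a profile from its
cyclic shifts or mirror image, so all comparisons against ground truth use
`align_correlation()`, which searches both exhaustively.

What recovery quality to expect: with 15 measured orders, even the
classical difference synthesis *with known native phases* reconstructs a
planted glycation density only to r ≈ 0.7–0.85 (the difference moduli
carry only the component of the glycation structure factor in phase with
the native one). The two-stage scheme with positivity reaches r ≈ 0.85–0.87
on clean synthetic pairs and degrades gracefully with noise; tests assert
r > 0.85 at the generator's default conditions with a fixed seed.

## Residue maps

The staggered repetition unit is rasterized at 1930 pixels per period with
the same pixel size axially and laterally; each residue is a unit-mass disk
of radius 2 px, strand rows sit d_E apart, and the axial direction wraps
periodically. Both class maps are blurred with a uniform disk whose
*diameter* equals the 4.3 nm resolution ("width" read as full extent —
configurable), and the pointwise product D_arg–lys marks positions where
both residue classes lie within about one resolution element. The lateral
canvas carries a margin of one disk diameter so blurring loses no mass.

The package ships no real collagen residue coordinates — the linearized
positions of the reference structure are not redistributable data — so the
residue-table format plus seeded synthetic tables (`gen_residue_table()`,
including a paired mode that plants proximity hotspots at known axial
positions) stand in. Correlations against real structures therefore cannot
be asserted by the tests; what the tests do show is that the chain is
mass-conserving, shift-equivariant, and separates planted hotspot
placements (r > 0.85) from disjoint ones (r ≈ 0).

## Period kinetics

Squared relative variations (d_t/d_0 − 1)² of both periods are fitted
against incubation time by ordinary least squares *with* intercept: on the
packaged series this reproduces all three published slopes within their
printed uncertainties, while through-origin fits (available via
`through_origin = TRUE`) do slightly worse. Because the squared quantity is
sign-blind, the reported slope carries a sign restored from the direction
of the raw period change (negative for the shrinking d_M). Measurement
errors are not propagated into weighted fits by default — the choice of
weights is not determined by the data tables — but `weights` is accepted.

## The glycation-rate model

The model chain is deliberately factored into small operations so each
reconstruction can be swapped independently:

* `sugar_molecules_in_cell()`: sugars dissolved in one repetition-unit
  volume, V = 21.9 nm² × d_M, at the bath concentration (linear in
  concentration; ≈230 ribose molecules at 40 mg/ml).
* `available_fraction()`: the free in-plane fraction
  w = 1 − (d_E0/d_Et)²(1 − w_nat), equal to w_nat = 0.255 before swelling.
  Predictions default to the native fraction.
* `effective_rate()`: R_AGE = c·(PSA_nat/TPSA)⁵. The fifth power mirrors
  the five molecules sharing the cell's free space. The orientation of the
  ratio is fixed by the physics (larger, more polar sugars permeate more
  slowly) and by the published rate values (c = 0.069/yr maps to
  0.064/yr for ribose only with PSA_nat in the numerator).
* `single_site_probability()`: `linear_capped` (min(Rt, 1), default) or
  `exponential` (1 − e^(−Rt)). The underlying probability law is not
  fully determined by the available description; both forms are shipped,
  agree to first order at small Rt, and the choice is logged in every
  report.
* `total_probability()`: 1 − (1 − P)^{N_s} — any of the N_s available
  sugar molecules can glycate a site.
* `calibrate_c()`: root-finds the single constant c so the predicted count
  matches an observed one (the 90-day ribose N = 36.8 by default). The
  objective is monotone in c, so the root is unique; the round trip
  calibrate → predict is exact to solver tolerance.

Two caveats are worth stating plainly. First, the electron-count
"detailed" estimate uses a constant geometry factor κ = 36.8/24 relating
the rough electron count to the detailed one for ribose at 90 days; the
same κ applied to glucose gives 5.1, not the published 8.2, so κ is
evidently not sugar-independent in the original treatment and we document
rather than hide the discrepancy. Second, our calibration under these
reconstructions yields c ≈ 0.041/yr, between the literature reference
accumulation rate (0.037/yr) and the published fit (0.069/yr); the exact
free-volume equations behind the published value are not available in the
main text, so `calibrate_c()` reports its own value and the deviation
instead of asserting agreement. With our c, the 10-year prediction at a
physiological blood concentration is ≈17% of sites for glucose and ≈51%
for ribose.

## The synthetic generator: what it emulates, and what it does not

`synthetic_scenario()` fixes the study conditions: d_M = 65.5 nm,
d_E = 1.514 nm, σ = 0.475, band contrast 0.055, 15 Bragg orders with
Gaussian instrumental width 0.008 nm⁻¹ on a 5 × 10⁻⁴/q² background,
per-point Gaussian noise at SNR 50 (Poisson-like counting noise in the
high-count synchrotron regime; the noise is proportional, not Poisson),
and linear-law time-series slopes 1.63 × 10⁻⁴/day (d_E), 3.1 × 10⁻⁶/day
(d_M), 1.26 × 10⁻⁴/day (contrast), with measurement noise at the printed
uncertainty scales (0.1 nm, 0.006 nm, 0.001).

The default planted glycation density is four Gaussian sites at fractional
positions {0.12, 0.33, 0.62, 0.85} with amplitudes {0.04, 0.05, 0.03,
0.045} (gap level = 1) and σ-widths ≈ 2 nm. Two considerations fixed these
once: features much narrower than the 4.3 nm resolution are not
representable in a 15-order reconstruction, so planted features live at the
resolution scale; and the site integrals sum to ≈0.0126 of the mean
density, matching the measured 90-day contrast increment of 0.012 for
ribose. Time-series generation inverts the fitted laws exactly
(d_E(t) = d_E0(1 + √(Δd_E·t)), etc.), so noiseless generation → fitting is
an identity test.

What the generator does *not* emulate: instrument smearing beyond a
Gaussian peak width, detector geometry, inter-sample variability, real
residue coordinates, and any deviation of the true native density from the
two-level model. Passing tests therefore demonstrate internal consistency
of the algorithms under realistic noise, not instrument-grade validation.

## Problem sizes and runtime

Default problem sizes were chosen so a complete analysis is interactive:
the phasing grid is 1930 points and a full 7 × (200 + 500)-iteration
refinement takes a few seconds; rasters are 1930 × ~450 px and blur via
FFT; the full test suite, including two end-to-end generate → index →
phase → correlate runs, finishes in about a minute on one core.

## Known limitations

* ρ_gl is reported without uncertainty quantification; the alternating
  projection scheme gives a point estimate only.
* The two-level contrast Δρ is taken from tabulated observables, never
  extracted from amplitudes (the zero order is unmeasured).
* The k·d_E² cell-area surrogate ignores the true packing angles; it is
  exact only under similarity scaling.
* The kinetics model inherits every simplification of its reconstruction:
  constant bath concentration, native free-volume fraction, a single
  global rate constant, and no collagen turnover.
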