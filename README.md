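# glycofibril

Quantitative analysis of non-enzymatic collagen glycation from small- and
wide-angle X-ray scattering (SAXS/WAXS).

Type I collagen fibrils are built from ~300 nm triple-helix molecules packed
in a staggered lattice with a meridional repeat d_M ≈ 65 nm and an equatorial
inter-molecule spacing d_E ≈ 1.5 nm. Reducing sugars (ribose, glucose)
attach irreversibly to lysine/hydroxylysine and arginine side chains —
glycation — stiffening the tissue; this is the structural link between
hyperglycemia and the vascular complications of diabetes. `glycofibril`
turns already-integrated 1D SAXS/WAXS profiles and per-timepoint lattice
observables into quantitative statements about where, how fast, and how much
a collagen matrix glycates.

## What the package computes

**Bragg analysis.** Meridional SAXS shows equispaced reflections at
q_n = 2πn/d_M. `index_meridional_peaks()` locates and integrates orders
1..15 over a local background, refines d_M, and extracts the moduli
|F_n| as square roots of net integrated intensities.
`fit_two_level_model()` fits the overlap/gap band model, whose order-n
modulus is proportional to |sin(πnσ)|/(πn), giving the overlap fraction
σ ≈ 0.475. `fit_d_E()` reads the equatorial spacing off the WAXS peak.

**Fourier-difference phasing.** The glycation electron-density profile
ρ_gl(x) = ρ_fin(x) − ρ_ini(x) over one period is retrieved by a two-stage
alternating-projection scheme (`phase_refine()`): stage 1 phases the native
and glycated densities jointly from a step-function start under measured
moduli and positivity, averaging the two trials for the first 90% of 200
iterations; stage 2 refines the difference density for 500 iterations with
the targets set to |ΔF_n| and positivity in real space; seven outer cycles
repeat the pair. Resolution is d_M/n_max = 65/15 ≈ 4.3 nm.

**Residue proximity model.** `rasterize_residues()`, `disk_blur()`, and
`proximity_map()` build D_arg–lys(x, y): the product of the arginine and
lysine/hydroxylysine occupancy maps, each blurred with a uniform disk the
size of the experimental resolution. Its axial projection is compared with
ρ_gl by Pearson correlation (`correlate_profiles()`), testing whether
glycation localizes at arginine–lysine contact sites.

**Period kinetics.** The squared relative variations
(d_Et/d_E0 − 1)² and (d_Mt/d_M0 − 1)² grow linearly with incubation time;
`fit_period_slope()` fits them by OLS, `slope_ratio()` forms the
ribose/glucose time-scale factor f, and `volume_change()` combines the two
slopes into the fibril volume-change rate ΔV = (Δd_E + 1)(Δd_M + 1) − 1.

**Glycation-rate model.** Electron counting converts the measured contrast
increment into bound-sugar numbers
(`electrons_from_contrast()` → `rough_molecule_count()` →
`detailed_molecule_count()`). The kinetics model sets the per-site rate to
R_AGE = c (PSA_nat / TPSA_sugar)^5 — sugars with larger topological polar
surface area permeate the inter-molecular free space more slowly — with
PSA_nat = 89 Å² derived from the native packing geometry. A per-site
probability P(t), aggregated over the N_s sugar molecules available in the
repetition-unit free volume as P_tot = 1 − (1 − P)^{N_s} and multiplied by
the Np = 86 crosslink-capable arginine–lysine pairs, predicts the glycated
fraction over years. `calibrate_c()` fixes the single free constant c from
an observed 90-day count.

A synthetic-data generator (`synthetic_scenario()`, `gen_density_pair()`,
`gen_saxs_profile()`, `gen_timeseries()`, `gen_residue_table()`) emulates
bovine-pericardium meridional scattering with planted ground truth, so
every stage is testable end to end without instrument data.

## Worked example

```r
library(glycofibril)

rep <- run_periods(incubation_series("ribose"), incubation_series("glucose"))
rep$outputs$slope_d_E
#> # A tibble: 1 × 5
#>      slope stderr_slope intercept r.squared sign_convention
#> 1 0.000163    0.0000174 0.0000486     0.967               1
rep$outputs$timescale_factor$nearest
#> [1] 38
```

The equatorial law for ribose has slope 1.63 × 10⁻⁴ per day (the lateral
lattice swells as sugars intercalate), and glucose follows the same law 38
times more slowly. Calibrating the rate model on the 90-day ribose count
and predicting glucose at a physiological blood concentration
(100 mg/dl = 1 mg/ml):

```r
cfg <- glycation_config()
cfg$c_rate <- as.numeric(
  calibrate_c(36.8, days_to_years(90), get_sugar("ribose"), 40, cfg))
predict_glycation(cfg, "glucose", 1, t_years = c(1, 5, 10))
#> # A tibble: 3 × 3
#>   t_years fraction n_glyc
#> 1       1   0.0174   1.49
#> 2       5   0.0863   7.43
#> 3      10   0.171   14.7
```

After ten years at a safe glucose level, about 17% of the available
arginine–lysine pairs are predicted to be glycated (≈15 of 86 sites per
repetition unit).

## Layout

- `R/` — geometry, SAXS profile handling, phasing, residue maps, kinetics,
  glycation model, generators, pipeline reports, plotting.
- `inst/extdata/` — packaged incubation series (ribose/glucose, 40 mg/ml)
  and the sugar registry.
- `vignettes/glycation-analysis.Rmd` — the methods vignette: model
  assumptions, parameter choices, numerical details, limitations.
- `tests/testthat/` — unit, property, and acceptance tests.
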