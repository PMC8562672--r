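# Synthetic-data generator. Emulates bovine-pericardium collagen meridional
# SAXS (d_M ~ 65.5 nm, >= 15 Bragg orders over a 1/q^2 background, two-level
# gap/overlap contrast with sigma ~ 0.475) plus the linear-in-time squared
# relative period variations of the incubation experiments, so that every
# pipeline stage can be exercised against a known ground truth.

#' Synthetic scenario
#'
#' Bundles every generator condition: the lattice, the two-level band
#' contrast, the planted glycation sites, instrument and noise parameters,
#' and the time-series slopes. All randomness is driven by `seed`.
#'
#' Default glycation sites are four Gaussian bumps with widths of 2 nm -
#' features at the scale of the 4.3 nm experimental resolution (anything much
#' narrower cannot be represented by a 15-order reconstruction) - whose
#' summed integral is about 0.0126 of the average density, matching the
#' measured 90-day contrast increment for ribose.
#'
#' @param seed Integer seed fixing all generator randomness.
#' @param lattice A [collagen_lattice()].
#' @param delta_rho_contrast Two-level overlap/gap contrast of the native
#'   density (gap level 1).
#' @param glycation_sites Tibble `x_frac, amplitude, width_nm` of planted
#'   Gaussian glycation features (width = Gaussian sigma, nm).
#' @param n_orders Bragg orders present in generated profiles.
#' @param background_amp Coefficient of the `1/q^2` diffuse background.
#' @param noise_snr Per-point signal-to-noise ratio (Gaussian noise with
#'   sd = intensity / SNR); `Inf` for noiseless.
#' @param peak_width_q Gaussian instrumental peak sigma in 1/nm.
#' @param timeseries_slopes Named list of the linear-law slopes
#'   (`d_E`, `d_M` for the squared relative variations, 1/day, and
#'   `delta_rho` for the contrast trend, 1/day).
#' @param delta_rho_0 Baseline contrast of the time series.
#' @param n_residues Named vector: residues per class for random tables.
#' @param noise_scales Named list of time-series noise scales (nm, nm, -).
#' @return A list of class `synthetic_scenario`.
#' @export
synthetic_scenario <- function(
    seed = 1,
    lattice = collagen_lattice(),
    delta_rho_contrast = 0.055,
    glycation_sites = tibble(
      x_frac = c(0.12, 0.33, 0.62, 0.85),
      amplitude = c(0.04, 0.05, 0.03, 0.045),
      width_nm = c(2.0, 2.4, 2.0, 2.2)
    ),
    n_orders = 15,
    background_amp = 5e-4,
    noise_snr = 50,
    peak_width_q = 0.008,
    timeseries_slopes = list(d_E = 1.63e-4, d_M = 3.1e-6, delta_rho = 1.26e-4),
    delta_rho_0 = 0.055,
    n_residues = c(arg = 30, lys = 30),
    noise_scales = list(d_M = 0.1, d_E = 0.006, delta_rho = 0.001)) {
  if (any(glycation_sites$x_frac < 0 | glycation_sites$x_frac >= 1)) {
    abort("glycation sites must lie in [0, 1).",
          class = "glycofibril_domain_error")
  }
  if (any(glycation_sites$width_nm <= 0)) {
    abort("site widths must be positive.", class = "glycofibril_domain_error")
  }
  structure(
    list(seed = as.integer(seed), lattice = lattice,
         delta_rho_contrast = delta_rho_contrast,
         glycation_sites = glycation_sites, n_orders = n_orders,
         background_amp = background_amp, noise_snr = noise_snr,
         peak_width_q = peak_width_q,
         timeseries_slopes = timeseries_slopes, delta_rho_0 = delta_rho_0,
         n_residues = n_residues, noise_scales = noise_scales),
    class = "synthetic_scenario"
  )
}

# Periodic Gaussian bump on the fractional grid.
.periodic_gaussian <- function(x, x0, amplitude, width_frac) {
  d <- ((x - x0 + 0.5) %% 1) - 0.5
  amplitude * exp(-0.5 * (d / width_frac)^2)
}

#' Generate a native/glycated density pair with known ground truth
#'
#' The native density is the two-level gap/overlap profile (gap level 1,
#' overlap level `1 + delta_rho_contrast`, overlap fraction `sigma`); the
#' glycation density is the sum of the scenario's Gaussian sites; the final
#' density is their sum.
#'
#' @param scenario A [synthetic_scenario()].
#' @param grid_size Grid points per period.
#' @return List of `axial_profile`s: `rho_ini`, `rho_fin`, `rho_gl`.
#' @export
gen_density_pair <- function(scenario, grid_size = 1930) {
  lat <- scenario$lattice
  x <- (seq_len(grid_size) - 1) / grid_size
  rho_ini <- 1 + scenario$delta_rho_contrast * (x < lat$sigma)
  sites <- scenario$glycation_sites
  rho_gl <- rep(0, grid_size)
  for (i in seq_len(nrow(sites))) {
    rho_gl <- rho_gl + .periodic_gaussian(
      x, sites$x_frac[i], sites$amplitude[i], sites$width_nm[i] / lat$d_M)
  }
  list(
    rho_ini = axial_profile(rho_ini, d_M = lat$d_M, role = "rho_ini"),
    rho_fin = axial_profile(rho_ini + rho_gl, d_M = lat$d_M, role = "rho_fin"),
    rho_gl = axial_profile(rho_gl, d_M = lat$d_M, role = "rho_gl")
  )
}

#' Fourier moduli of an axial density
#'
#' `|F_n| = |sum_j rho_j exp(-2 pi i n j / N)| / N` for the requested orders.
#'
#' @param profile An `axial_profile` or numeric vector.
#' @param orders Bragg orders.
#' @return Named numeric vector of moduli.
#' @export
density_moduli <- function(profile, orders = 1:15) {
  v <- if (inherits(profile, "axial_profile")) profile$value else profile
  m <- Mod(fft(v))[orders + 1] / length(v)
  setNames(m, orders)
}

#' Generate a synthetic SAXS profile from a density
#'
#' Places Gaussian Bragg peaks at `q_n = 2 pi n / d_M` whose integrated
#' intensities are the squared Fourier moduli of the density, adds a
#' `1/q^2` diffuse background, and applies seeded Gaussian noise with
#' per-point sd `intensity / noise_snr`.
#'
#' @param density An `axial_profile` (typically from [gen_density_pair()]).
#' @param scenario A [synthetic_scenario()].
#' @param q_step q-grid spacing, 1/nm.
#' @param seed_offset Added to the scenario seed (so the native and glycated
#'   profiles of one pair get independent noise).
#' @return A [saxs_profile()].
#' @export
gen_saxs_profile <- function(density, scenario, q_step = 8e-4,
                             seed_offset = 0) {
  lat <- scenario$lattice
  moduli <- density_moduli(density, seq_len(scenario$n_orders))
  spacing <- 2 * pi / lat$d_M
  q <- seq(0.3 * spacing, (scenario$n_orders + 0.7) * spacing, by = q_step)
  intensity <- scenario$background_amp / q^2
  w <- scenario$peak_width_q
  for (n in seq_len(scenario$n_orders)) {
    qn <- spacing * n
    intensity <- intensity +
      moduli[n]^2 * exp(-0.5 * ((q - qn) / w)^2) / (w * sqrt(2 * pi))
  }
  if (is.finite(scenario$noise_snr)) {
    set.seed(scenario$seed + seed_offset)
    intensity <- intensity +
      rnorm(length(q), 0, intensity / scenario$noise_snr)
    intensity <- pmax(intensity, 0)
  }
  saxs_profile(q, intensity, kind = "SAXS",
               label = sprintf("synthetic_%s", attr(density, "role")))
}

#' Generate a lattice observable time series obeying the linear laws
#'
#' `d_E(t) = d_E0 (1 + sqrt(slope_dE t))`, `d_M(t) = d_M0 (1 - sqrt(slope_dM
#' t))`, `delta_rho(t) = delta_rho_0 + rate t`, plus seeded Gaussian noise at
#' the scenario's measurement-error scales.
#'
#' @param scenario A [synthetic_scenario()].
#' @param t_days Time points, starting at 0.
#' @param noise Apply measurement noise (the `t = 0` baseline is always
#'   noise-free so the squared relative variations stay anchored).
#' @return A `lattice_series` tibble.
#' @export
gen_timeseries <- function(scenario, t_days = c(0, 3, 14, 30, 90),
                           noise = TRUE) {
  if (t_days[1] != 0) abort("`t_days` must start at 0.",
                            class = "glycofibril_domain_error")
  sl <- scenario$timeseries_slopes
  if (sl$d_E < 0) abort("`d_E` slope must be non-negative.",
                        class = "glycofibril_domain_error")
  lat <- scenario$lattice
  d_E <- lat$d_E * (1 + sqrt(sl$d_E * t_days))
  d_M <- lat$d_M * (1 - sqrt(abs(sl$d_M) * t_days))
  delta_rho <- scenario$delta_rho_0 + sl$delta_rho * t_days
  if (noise) {
    set.seed(scenario$seed)
    ns <- scenario$noise_scales
    jitter <- function(v, s) c(v[1], v[-1] + rnorm(length(v) - 1, 0, s))
    d_E <- jitter(d_E, ns$d_E)
    d_M <- jitter(d_M, ns$d_M)
    delta_rho <- jitter(delta_rho, ns$delta_rho)
  }
  lattice_series(t_days, d_M, d_E, delta_rho,
                 d_M_err = scenario$noise_scales$d_M,
                 d_E_err = scenario$noise_scales$d_E,
                 delta_rho_err = scenario$noise_scales$delta_rho,
                 sugar = "synthetic", concentration = 40)
}

#' Generate a residue table
#'
#' Random mode scatters the requested number of arginine and
#' lysine/hydroxylysine residues uniformly over the strands and the period.
#' Paired mode instead places arginine-lysine pairs around stated axial
#' hotspots (within `hotspot_tol` of the hotspot coordinate, same strand
#' neighbourhood), planting proximity maxima at known positions.
#'
#' @param scenario A [synthetic_scenario()].
#' @param mode `"random"` or `"paired"`.
#' @param hotspot_x Axial hotspot coordinates for paired mode.
#' @param hotspot_tol Maximal axial offset of a paired residue from its
#'   hotspot (fractional units).
#' @return A [residue_table()].
#' @export
gen_residue_table <- function(scenario, mode = c("random", "paired"),
                              hotspot_x = c(0.2, 0.7), hotspot_tol = 0.01) {
  mode <- match.arg(mode)
  set.seed(scenario$seed + 1)
  n_strands <- scenario$lattice$n_strands
  n_arg <- scenario$n_residues[["arg"]]
  n_lys <- scenario$n_residues[["lys"]]
  if (n_arg < 1 || n_lys < 1) {
    abort("need at least one residue per class.",
          class = "glycofibril_domain_error")
  }
  if (mode == "random") {
    tab <- residue_table(
      strand_row = sample(0:(n_strands - 1), n_arg + n_lys, replace = TRUE),
      x_frac = runif(n_arg + n_lys),
      residue_class = c(rep("ARG", n_arg), rep("LYS_HYL", n_lys))
    )
  } else {
    n_pairs <- max(length(hotspot_x), ceiling(min(n_arg, n_lys) / 2))
    hx <- rep(hotspot_x, length.out = n_pairs)
    rows <- sample(0:(n_strands - 1), n_pairs, replace = TRUE)
    wob <- function(x) (x + runif(length(x), -hotspot_tol, hotspot_tol)) %% 1
    tab <- residue_table(
      strand_row = c(rows, rows),
      x_frac = c(wob(hx), wob(hx)),
      residue_class = c(rep("ARG", n_pairs), rep("LYS_HYL", n_pairs))
    )
  }
  tab
}
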