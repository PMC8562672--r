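# Sugar-dependent glycation kinetics. Electron counting converts the measured
# contrast increment into a number of bound sugar molecules; the rate model
# scales a single fitted constant c by the inverse fifth power of the sugar's
# topological polar surface area relative to the native packing reference
# (PSA_nat), feeds a per-site glycation probability, aggregates over the
# sugar molecules available in the free volume of one staggered repetition
# unit, and multiplies by the number of crosslink-capable arginine-lysine
# pairs to predict glycated-site counts over years.

.days_per_year <- 365

#' Glycation model configuration
#'
#' One auditable record of every constant the kinetics model uses.
#'
#' @param c_rate Rate constant `c` in 1/year (`NA` until calibrated).
#' @param psa_nat Reference polar surface area of the native packing,
#'   Angstrom^2.
#' @param psa_exponent Exponent of the PSA ratio (default 5, one per
#'   laterally staggered molecule of the in-plane cell).
#' @param n_pairs Arginine-lysine/hydroxylysine pairs close enough for
#'   crosslink formation per staggered repetition unit.
#' @param n_electrons Electrons per collagen molecule.
#' @param r_age_reference Literature reference accumulation rate, 1/year,
#'   for comparison in reports.
#' @param probability_form `"linear_capped"` (`min(R t, 1)`) or
#'   `"exponential"` (`1 - exp(-R t)`).
#' @param kappa Geometry correction multiplying the rough electron-count
#'   molecule estimate in the detailed count (default calibrated so the
#'   90-day ribose point gives the detailed estimate 36.8 from the rough 24).
#' @param lattice A [collagen_lattice()] used for unit-cell volumes.
#' @param w_nat Native free in-plane area fraction.
#' @param registry Sugar registry tibble.
#' @return A list of class `glycation_config`.
#' @export
glycation_config <- function(c_rate = NA_real_, psa_nat = 89,
                             psa_exponent = 5, n_pairs = 86,
                             n_electrons = 160000, r_age_reference = 0.037,
                             probability_form = c("linear_capped",
                                                  "exponential"),
                             kappa = 36.8 / 24,
                             lattice = collagen_lattice(),
                             w_nat = 0.255,
                             registry = sugar_registry()) {
  probability_form <- match.arg(probability_form)
  stopifnot(psa_nat > 0, psa_exponent > 0, n_pairs > 0, n_electrons > 0,
            kappa > 0, w_nat > 0, w_nat < 1)
  structure(
    list(c_rate = c_rate, psa_nat = psa_nat, psa_exponent = psa_exponent,
         n_pairs = n_pairs, n_electrons = n_electrons,
         r_age_reference = r_age_reference,
         probability_form = probability_form, kappa = kappa,
         lattice = lattice, w_nat = w_nat, registry = registry),
    class = "glycation_config"
  )
}

#' @export
print.glycation_config <- function(x, ...) {
  cat("<glycation_config>\n")
  cat(sprintf("  c = %s /yr, PSA_nat = %.1f A^2 (exponent %g), Np = %d, N_e = %d\n",
              ifelse(is.na(x$c_rate), "uncalibrated", format(x$c_rate)),
              x$psa_nat, x$psa_exponent, x$n_pairs, x$n_electrons))
  cat(sprintf("  probability form: %s, kappa = %.4g, w_nat = %.3f\n",
              x$probability_form, x$kappa, x$w_nat))
  invisible(x)
}

#' Electrons added per molecule from a contrast increment
#'
#' The increase of the relative overlap/gap density contrast between two
#' incubation endpoints, multiplied by the electrons per collagen molecule,
#' counts the electrons added by bound sugars.
#'
#' @param delta_delta_rho Contrast increment (endpoint difference of
#'   `delta_rho`), in `[0, 1)`.
#' @param n_electrons Electrons per collagen molecule.
#' @return Electron count.
#' @examples
#' electrons_from_contrast(0.012) # 1920
#' @export
electrons_from_contrast <- function(delta_delta_rho, n_electrons = 160000) {
  if (any(delta_delta_rho < 0 | delta_delta_rho >= 1)) {
    abort("`delta_delta_rho` must lie in [0, 1).",
          class = "glycofibril_domain_error")
  }
  delta_delta_rho * n_electrons
}

#' Rough bound-molecule count from an electron count
#'
#' @param electrons Added electrons (>= 0).
#' @param sugar A sugar record from [get_sugar()].
#' @return List with `molecules` (real) and `rounded` (integer for
#'   reporting).
#' @examples
#' rough_molecule_count(1920, get_sugar("ribose"))$rounded # 24
#' @export
rough_molecule_count <- function(electrons, sugar) {
  if (any(electrons < 0)) abort("`electrons` must be non-negative.",
                                class = "glycofibril_domain_error")
  m <- electrons / sugar$electrons
  list(molecules = m, rounded = as.integer(round(m)))
}

#' Detailed bound-molecule count
#'
#' The rough electron-count estimate multiplied by a geometry correction
#' `kappa` accounting for how the added density distributes over the
#' staggered repetition unit. With the default `kappa` the 90-day ribose
#' contrast increment reproduces the detailed estimate 36.8; `kappa = 1`
#' reduces to the rough count.
#'
#' @inheritParams electrons_from_contrast
#' @param sugar A sugar record from [get_sugar()].
#' @param config A [glycation_config()].
#' @return Real-valued molecule count.
#' @export
detailed_molecule_count <- function(delta_delta_rho, sugar,
                                    config = glycation_config()) {
  config$kappa *
    electrons_from_contrast(delta_delta_rho, config$n_electrons) /
    sugar$electrons
}

#' Sugar molecules in the repetition-unit volume
#'
#' Number of dissolved sugar molecules in a volume of solution equal to the
#' volume of one staggered repetition unit (swollen in-plane unit-cell area
#' times the D-period).
#'
#' @param concentration Sugar concentration, mg/ml.
#' @param sugar A sugar record from [get_sugar()].
#' @param lattice A [collagen_lattice()].
#' @return Real-valued molecule count (linear in concentration).
#' @examples
#' sugar_molecules_in_cell(40, get_sugar("ribose")) # ~230
#' @export
sugar_molecules_in_cell <- function(concentration, sugar,
                                    lattice = collagen_lattice()) {
  if (any(concentration < 0)) {
    abort("`concentration` must be non-negative.",
          class = "glycofibril_domain_error")
  }
  avogadro <- 6.02214076e23
  v_cell_nm3 <- unit_cell_area(lattice$d_E, "swollen") * lattice$d_M
  v_cell_cm3 <- v_cell_nm3 * 1e-21
  # concentration mg/ml = 1e-3 g/cm^3
  (concentration * 1e-3 / sugar$molar_mass) * avogadro * v_cell_cm3
}

#' Free-volume fraction available to sugars
#'
#' Fraction of the in-plane cell between the (cylindrical) collagen
#' molecules: `w = 1 - (d_E_0 / d_E_t)^2 * (1 - w_nat)`, equal to `w_nat`
#' before any swelling and growing as the lattice expands.
#'
#' @param d_E_t,d_E_0 Equatorial spacing at time t and at baseline, nm.
#' @param w_nat Native free fraction.
#' @return Fraction in `[w_nat, 1)`.
#' @examples
#' available_fraction(1.695, 1.514) # ~0.41
#' @export
available_fraction <- function(d_E_t, d_E_0 = d_E_t, w_nat = 0.255) {
  if (any(d_E_0 <= 0)) abort("`d_E_0` must be positive.",
                             class = "glycofibril_domain_error")
  if (any(d_E_t < d_E_0)) {
    warn("shrinking lattice (d_E_t < d_E_0); flooring at w_nat.")
  }
  pmax(1 - (d_E_0 / d_E_t)^2 * (1 - w_nat), w_nat)
}

#' Sugar-specific glycation rate
#'
#' `R_AGE = c * (PSA_nat / TPSA_sugar)^exponent`: a sugar with a larger polar
#' surface area fits the inter-molecular free space less easily and glycates
#' more slowly.
#'
#' @param config A calibrated [glycation_config()].
#' @param sugar A sugar record from [get_sugar()].
#' @return Rate in 1/year.
#' @export
effective_rate <- function(config, sugar) {
  if (is.na(config$c_rate)) {
    abort("config has no calibrated `c_rate`.",
          class = "glycofibril_domain_error")
  }
  config$c_rate * (config$psa_nat / sugar$tpsa)^config$psa_exponent
}

#' Per-site glycation probability
#'
#' @param t_years Times in years (>= 0).
#' @param rate Glycation rate, 1/year.
#' @param form `"linear_capped"` (`min(rate * t, 1)`) or `"exponential"`
#'   (`1 - exp(-rate * t)`).
#' @return Probabilities in `[0, 1]`, non-decreasing in `t_years`.
#' @export
single_site_probability <- function(t_years, rate,
                                    form = c("linear_capped", "exponential")) {
  form <- match.arg(form)
  if (any(t_years < 0)) abort("`t_years` must be non-negative.",
                              class = "glycofibril_domain_error")
  switch(form,
         linear_capped = pmin(rate * t_years, 1),
         exponential = 1 - exp(-rate * t_years))
}

#' Total glycation probability over the available sugar molecules
#'
#' If any one of `n_s` independent sugar molecules can glycate a site, the
#' site's total probability is `1 - (1 - p)^n_s` (real-valued `n_s`
#' permitted).
#'
#' @param p Per-molecule probability in `[0, 1]`.
#' @param n_s Effective number of available sugar molecules (>= 0).
#' @return Total probability in `[0, 1]`.
#' @export
total_probability <- function(p, n_s) {
  if (any(p < 0 | p > 1)) abort("`p` must lie in [0, 1].",
                                class = "glycofibril_domain_error")
  if (any(n_s < 0)) abort("`n_s` must be non-negative.",
                          class = "glycofibril_domain_error")
  1 - (1 - p)^n_s
}

#' Expected number of glycated sites
#'
#' @param p_tot Total per-site probability.
#' @param n_pairs Available arginine-lysine/hydroxylysine pairs.
#' @return Expected glycation count in `[0, n_pairs]`.
#' @export
n_glycations <- function(p_tot, n_pairs = 86) {
  n_pairs * p_tot
}

# Effective sugar count per site for a concentration, under the documented
# free-volume reconstruction (w at the native packing unless a swollen d_E
# is supplied).
.effective_n_s <- function(config, sugar, concentration, d_E_t = NULL) {
  w <- if (is.null(d_E_t)) config$w_nat else
    available_fraction(d_E_t, config$lattice$d_E, config$w_nat)
  sugar_molecules_in_cell(concentration, sugar, config$lattice) * w
}

#' Calibrate the rate constant c
#'
#' Finds `c` such that the predicted glycation count at the observation time
#' equals the observed count, by bracketed root finding (the objective is
#' monotone in `c`, so the root is unique).
#'
#' @param observed_N Observed glycated-molecule count, in `(0, n_pairs)`.
#' @param t_obs_years Observation time in years.
#' @param sugar A sugar record from [get_sugar()].
#' @param concentration Sugar concentration, mg/ml.
#' @param config A [glycation_config()].
#' @param d_E_t Optional swollen equatorial spacing at the observation time
#'   (default: native free fraction is used).
#' @return The calibrated `c` (1/year), with attribute
#'   `reference_deviation` giving `c - r_age_reference`.
#' @export
calibrate_c <- function(observed_N, t_obs_years, sugar, concentration,
                        config = glycation_config(), d_E_t = NULL) {
  if (!(observed_N > 0 && observed_N < config$n_pairs)) {
    abort("`observed_N` must lie strictly between 0 and n_pairs.",
          class = "glycofibril_domain_error")
  }
  n_s <- .effective_n_s(config, sugar, concentration, d_E_t)
  psa_factor <- (config$psa_nat / sugar$tpsa)^config$psa_exponent
  objective <- function(c_try) {
    p <- single_site_probability(t_obs_years, c_try * psa_factor,
                                 config$probability_form)
    n_glycations(total_probability(p, n_s), config$n_pairs) - observed_N
  }
  upper <- 1
  while (objective(upper) < 0 && upper < 1e6) upper <- upper * 10
  if (objective(upper) < 0) {
    abort("calibration target unreachable.",
          class = "glycofibril_domain_error")
  }
  root <- uniroot(objective, lower = 0, upper = upper, tol = 1e-12)
  c_hat <- root$root
  attr(c_hat, "reference_deviation") <- c_hat - config$r_age_reference
  c_hat
}

#' Predict glycation fractions over time
#'
#' Evaluates the calibrated model on a time grid: the effective available
#' sugar count `N_s` (molecules in the repetition-unit volume times the free
#' in-plane fraction, linear in concentration), the per-site probability at
#' the sugar-specific rate, the total probability over `N_s` molecules, and
#' the expected glycated-site count.
#'
#' @param config A calibrated [glycation_config()].
#' @param sugar Sugar name or record.
#' @param concentration Sugar concentration, mg/ml.
#' @param t_years Time grid in years (non-empty, >= 0).
#' @param d_E_t Optional swollen equatorial spacing (default native).
#' @return A tibble of class `glycation_prediction` with columns `t_years`,
#'   `fraction`, `n_glyc`; attributes `sugar`, `concentration`, `n_s`,
#'   `rate`.
#' @export
predict_glycation <- function(config, sugar, concentration,
                              t_years = seq(0, 10, by = 0.1),
                              d_E_t = NULL) {
  if (length(t_years) == 0) abort("empty time grid.",
                                  class = "glycofibril_domain_error")
  if (is.character(sugar)) sugar <- get_sugar(sugar, config$registry)
  rate <- effective_rate(config, sugar)
  n_s <- .effective_n_s(config, sugar, concentration, d_E_t)
  p <- single_site_probability(t_years, rate, config$probability_form)
  p_tot <- total_probability(p, n_s)
  out <- tibble(t_years = t_years, fraction = p_tot,
                n_glyc = n_glycations(p_tot, config$n_pairs))
  class(out) <- c("glycation_prediction", class(out))
  attr(out, "sugar") <- sugar$name
  attr(out, "concentration") <- concentration
  attr(out, "n_s") <- n_s
  attr(out, "rate") <- rate
  out
}

#' Relative fibril volume change over time
#'
#' Scales the saturation volume increment by the total glycation
#' probability: `dV(t) = delta_v_sat * P_tot(t)`, a monotone curve
#' approaching `delta_v_sat`.
#'
#' @inheritParams predict_glycation
#' @param delta_v_sat Saturation relative volume increment (e.g. 0.36 for
#'   ribose, 0.10 for glucose).
#' @return A tibble with `t_years` and `delta_v`.
#' @export
volume_curve <- function(config, sugar, concentration, delta_v_sat,
                         t_years = seq(0, 10, by = 0.1), d_E_t = NULL) {
  if (delta_v_sat < 0) abort("`delta_v_sat` must be non-negative.",
                             class = "glycofibril_domain_error")
  pred <- predict_glycation(config, sugar, concentration, t_years, d_E_t)
  tibble(t_years = pred$t_years, delta_v = delta_v_sat * pred$fraction)
}

#' Convert incubation days to years
#'
#' @param t_days Days.
#' @return Years at 365 days/year.
#' @export
days_to_years <- function(t_days) t_days / .days_per_year
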