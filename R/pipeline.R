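# Orchestration: one function per analysis stage, each returning a
# serializable run report (inputs echo, per-stage outputs, warnings, seed,
# package version) so complete runs are reproducible and auditable.

.new_report <- function(stage, inputs, outputs, warnings = character(),
                        seed = NA_integer_) {
  structure(
    list(stage = stage, inputs = inputs, outputs = outputs,
         warnings = warnings, seed = seed,
         version = as.character(utils::packageVersion("glycofibril")),
         timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")),
    class = "glycofibril_report"
  )
}

#' @export
print.glycofibril_report <- function(x, ...) {
  cat(sprintf("<glycofibril_report: %s> (v%s)\n", x$stage, x$version))
  utils::str(x$outputs, max.level = 2, give.attr = FALSE)
  if (length(x$warnings)) cat("warnings:", paste(x$warnings, collapse = "; "), "\n")
  invisible(x)
}

#' Serialize a run report to JSON
#'
#' @param report A report from one of the `run_*` functions.
#' @param path Output JSON path.
#' @return `path`, invisibly.
#' @export
write_report <- function(report, path) {
  clean <- rapply(unclass(report), function(x) {
    if (is_tibble(x)) as.data.frame(x) else x
  }, how = "replace", classes = "ANY")
  jsonlite::write_json(clean, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "columns", force = TRUE)
  invisible(path)
}

#' Period-kinetics stage
#'
#' Fits the linear laws of the squared relative period variations and the
#' density-contrast trend for one series; when a second series is given,
#' also the equatorial time-scale factor between the two, and the fibril
#' volume-change rate.
#'
#' @param series A `lattice_series` or CSV path.
#' @param series_b Optional second series (or path) for the slope ratio
#'   (convention: `series` / `series_b`, e.g. ribose over glucose).
#' @return A `glycofibril_report` whose `outputs` hold the fitted slopes,
#'   the ratio, the volume-change rate, and the contrast trend.
#' @export
run_periods <- function(series, series_b = NULL) {
  if (is.character(series)) series <- read_lattice_series(series)
  if (is.character(series_b)) series_b <- read_lattice_series(series_b)
  fit_E <- fit_period_slope(series, "d_E")
  fit_M <- fit_period_slope(series, "d_M")
  trend <- delta_rho_trend(series)
  outputs <- list(
    sugar = series$sugar[1],
    slope_d_E = glance(fit_E),
    slope_d_M = glance(fit_M),
    delta_rho_trend = glance(trend),
    volume_change = volume_change(fit_E, fit_M)
  )
  if (!is.null(series_b)) {
    fit_E_b <- fit_period_slope(series_b, "d_E")
    outputs$slope_d_E_b <- glance(fit_E_b)
    outputs$timescale_factor <- slope_ratio(fit_E, fit_E_b)
  }
  .new_report("periods",
              list(n_timepoints = nrow(series),
                   sugar = series$sugar[1],
                   concentration = series$concentration[1]),
              outputs)
}

#' Phasing stage
#'
#' Runs the full two-stage Fourier-difference phasing on a native/glycated
#' pair of indexed peak sets.
#'
#' @param peaks_native,peaks_glycated `saxs_peaks` tibbles (or CSV paths)
#'   sharing the same Bragg orders.
#' @param config A [phasing_config()].
#' @param grid_size Grid points per period.
#' @return A `glycofibril_report` with the retrieved `rho_gl`
#'   (`axial_profile` in `outputs$rho_gl`), per-cycle residuals, and the
#'   recorded resolution.
#' @export
run_phase <- function(peaks_native, peaks_glycated,
                      config = phasing_config(), grid_size = 1930) {
  if (is.character(peaks_native)) peaks_native <- read_peaks(peaks_native)
  if (is.character(peaks_glycated)) peaks_glycated <- read_peaks(peaks_glycated)
  orders <- config$measured_orders
  m_ini <- peak_moduli(peaks_native, orders)
  m_fin <- peak_moduli(peaks_glycated, orders)
  d_M <- attr(peaks_native, "d_M") %||% 65.5
  result <- phase_refine(m_ini, m_fin, config, grid_size = grid_size,
                         d_M = d_M)
  .new_report("phase",
              list(orders = orders, d_M = d_M, grid_size = grid_size),
              list(rho_gl = result$rho_gl,
                   cycle_log = result$cycle_log,
                   resolution_nm = result$resolution_nm,
                   result = result))
}

#' Residue-map stage
#'
#' Builds the blurred arginine-lysine proximity model from a residue table,
#' projects it to the axial coordinate, and correlates it with a retrieved
#' glycation profile.
#'
#' @param residues A `residue_table` (or CSV path).
#' @param rho_gl An `axial_profile` (or CSV path).
#' @param lattice A [collagen_lattice()].
#' @param R_nm Resolution-disk diameter in nm.
#' @param x_pixels Raster width.
#' @return A `glycofibril_report` with the axial proximity model and the
#'   Pearson correlation.
#' @export
run_map <- function(residues, rho_gl, lattice = collagen_lattice(),
                    R_nm = 4.3, x_pixels = 1930) {
  if (is.character(residues)) residues <- read_residue_table(residues)
  if (is.character(rho_gl)) rho_gl <- read_axial_profile(rho_gl)
  classes <- unique(residues$residue_class)
  if (!all(c("ARG", "LYS_HYL") %in% classes)) {
    abort("need residues of both classes for a proximity analysis.",
          class = "glycofibril_domain_error")
  }
  raster <- rasterize_residues(residues, lattice, x_pixels = x_pixels)
  D <- proximity_map(raster$map_arg, raster$map_lys, R_nm, lattice, x_pixels)
  model <- project_axial(D, lattice)
  comp <- correlate_profiles(model, rho_gl)
  .new_report("map",
              list(n_residues = nrow(residues), R_nm = R_nm,
                   x_pixels = x_pixels),
              list(correlation = comp$r, model = model,
                   profiles = comp$profiles))
}

#' Kinetics-model stage
#'
#' Calibrates the rate constant on an observed glycation count (unless `c`
#' is already set) and predicts glycation fractions for the requested
#' sugars/concentrations.
#'
#' @param config A [glycation_config()].
#' @param observed_N Calibration target count (ignored when `config$c_rate`
#'   is already set).
#' @param t_obs_years Calibration observation time, years.
#' @param cal_sugar,cal_concentration Calibration sugar and concentration.
#' @param predictions A tibble `sugar, concentration` of curves to compute.
#' @param t_years Prediction time grid.
#' @return A `glycofibril_report` with the calibrated `c` and one
#'   `glycation_prediction` per requested curve.
#' @export
run_kinetics <- function(config = glycation_config(),
                         observed_N = 36.8, t_obs_years = 90 / 365,
                         cal_sugar = "ribose", cal_concentration = 40,
                         predictions = tibble(
                           sugar = c("ribose", "glucose"),
                           concentration = c(40, 40)),
                         t_years = seq(0, 10, by = 0.1)) {
  if (is.na(config$c_rate)) {
    sugar <- get_sugar(cal_sugar, config$registry)
    config$c_rate <- as.numeric(
      calibrate_c(observed_N, t_obs_years, sugar, cal_concentration, config))
  }
  curves <- purrr::pmap(predictions, function(sugar, concentration) {
    predict_glycation(config, sugar, concentration, t_years)
  })
  names(curves) <- paste0(predictions$sugar, "_", predictions$concentration)
  .new_report("kinetics",
              list(observed_N = observed_N, t_obs_years = t_obs_years,
                   cal_sugar = cal_sugar,
                   cal_concentration = cal_concentration,
                   probability_form = config$probability_form),
              list(c_rate = config$c_rate,
                   reference_deviation = config$c_rate - config$r_age_reference,
                   curves = curves))
}
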