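# Two-stage iterative Fourier-difference phasing. Retrieves the glycation
# electron-density profile rho_gl over one D-period from the Bragg moduli of
# the native (rho_ini) and glycated (rho_fin = rho_ini + rho_gl) states,
# using alternating projections in error-reduction form: a modulus projector
# on the measured orders and a positivity projector in real space. Only the
# measured orders (default 1..15) are constrained; order 0 and all unmeasured
# harmonics are shaped by positivity alone, so solutions carry the usual
# phase-retrieval ambiguity of cyclic shift and mirror inversion.

#' Axial electron-density profile over one D-period
#'
#' @param values Density values on a uniform grid covering one period.
#' @param d_M Period in nm.
#' @param role One of `"rho_ini"`, `"rho_fin"`, `"rho_gl"`, `"rho_model"`.
#' @return A tibble of class `axial_profile` with columns `x_frac` (fractional
#'   period coordinate in `[0, 1)`) and `value`, and attributes `d_M`, `role`.
#' @export
axial_profile <- function(values, d_M = 65.5,
                          role = c("rho_ini", "rho_fin", "rho_gl", "rho_model")) {
  role <- match.arg(role)
  n <- length(values)
  if (n < 4) abort("grid too small.", class = "glycofibril_domain_error")
  out <- tibble(x_frac = (seq_len(n) - 1) / n, value = as.numeric(values))
  class(out) <- c("axial_profile", class(out))
  attr(out, "d_M") <- d_M
  attr(out, "role") <- role
  out
}

.profile_values <- function(x) {
  if (inherits(x, "axial_profile")) x$value else as.numeric(x)
}

.rewrap <- function(values, template) {
  axial_profile(values, d_M = attr(template, "d_M") %||% 65.5,
                role = attr(template, "role") %||% "rho_model")
}

#' Step-function starting model
#'
#' The minimal a-priori starting model for phasing: 1 in the first half of the
#' period, 0 in the second half.
#'
#' @param grid_size Points per period (>= 4).
#' @param d_M Period in nm.
#' @return An `axial_profile`.
#' @examples
#' step_start(4)$value # 1 1 0 0
#' @export
step_start <- function(grid_size = 1930, d_M = 65.5) {
  if (grid_size < 4) abort("`grid_size` must be >= 4.",
                           class = "glycofibril_domain_error")
  half <- ceiling(grid_size / 2)
  axial_profile(c(rep(1, half), rep(0, grid_size - half)), d_M = d_M,
                role = "rho_model")
}

#' Phasing configuration
#'
#' @param stage1_iters Iterations of the coupled first stage.
#' @param stage2_iters Iterations of the Fourier-difference second stage.
#' @param outer_cycles Outer refinement cycles (each = stage 1 + stage 2).
#' @param averaging_fraction Fraction of stage-1 iterations during which the
#'   two trial solutions are replaced by their average.
#' @param measured_orders Bragg orders constrained in Fourier space.
#' @param positivity_tol Tolerance of the positivity projector.
#' @return A list of class `phasing_config`.
#' @export
phasing_config <- function(stage1_iters = 200, stage2_iters = 500,
                           outer_cycles = 7, averaging_fraction = 0.9,
                           measured_orders = 1:15, positivity_tol = 0) {
  stopifnot(stage1_iters >= 1, stage2_iters >= 1, outer_cycles >= 1,
            averaging_fraction > 0, averaging_fraction <= 1,
            length(measured_orders) >= 1, all(measured_orders >= 1),
            positivity_tol >= 0)
  structure(
    list(stage1_iters = as.integer(stage1_iters),
         stage2_iters = as.integer(stage2_iters),
         outer_cycles = as.integer(outer_cycles),
         averaging_fraction = averaging_fraction,
         measured_orders = as.integer(measured_orders),
         positivity_tol = positivity_tol),
    class = "phasing_config"
  )
}

# Modulus projector on a plain numeric vector. Replaces the modulus at each
# measured order (+/- n) by the target, keeping the current phase (phase 0 if
# the current modulus vanishes). Order 0 and unmeasured orders untouched.
.project_modulus_vec <- function(values, targets, orders) {
  n <- length(values)
  if (any(orders >= n / 2)) {
    abort("measured order >= grid_size / 2.", class = "glycofibril_domain_error")
  }
  F <- fft(values)
  for (i in seq_along(orders)) {
    k <- orders[i]
    cur <- F[k + 1]
    mod <- Mod(cur)
    tgt <- n * targets[i]                 # fft() is unnormalized
    F[k + 1] <- if (mod > 0) tgt * cur / mod else tgt + 0i
    F[n - k + 1] <- Conj(F[k + 1])
  }
  Re(fft(F, inverse = TRUE)) / n
}

.modulus_residual <- function(values, targets, orders) {
  m <- Mod(fft(values))[orders + 1] / length(values)
  sqrt(sum((m - targets)^2)) / max(sqrt(sum(targets^2)), .Machine$double.eps)
}

#' Fourier-modulus projector
#'
#' Takes the discrete Fourier transform of the profile, replaces the modulus
#' at each measured order by its target while keeping the current phase, and
#' transforms back (real part). Moduli are on the convention
#' `|F_n| = |sum_j rho_j exp(-2 pi i n j / N)| / N`.
#'
#' @param profile An `axial_profile` (or numeric vector).
#' @param targets Non-negative target moduli, one per measured order.
#' @param orders Measured Bragg orders.
#' @return Projected `axial_profile`.
#' @export
project_modulus <- function(profile, targets, orders = seq_along(targets)) {
  if (any(targets < 0)) abort("target moduli must be non-negative.",
                              class = "glycofibril_domain_error")
  vals <- .project_modulus_vec(.profile_values(profile), targets, orders)
  if (inherits(profile, "axial_profile")) .rewrap(vals, profile) else vals
}

#' Positivity projector
#'
#' Clips the density at zero: values below `-tol` and small negatives within
#' `tol` are both set to 0.
#'
#' @param profile An `axial_profile` (or numeric vector).
#' @param tol Non-negative tolerance.
#' @return Projected `axial_profile`.
#' @export
project_positive <- function(profile, tol = 0) {
  if (tol < 0) abort("`tol` must be non-negative.",
                     class = "glycofibril_domain_error")
  # all negatives are clipped; `tol` documents the scale below which
  # negatives are regarded as numerical noise rather than constraint breaks
  vals <- pmax(.profile_values(profile), 0)
  if (inherits(profile, "axial_profile")) .rewrap(vals, profile) else vals
}

# One alternating-projection stage on a single trial; tracks the modulus
# residual for the divergence guard and the end-of-stage monotonicity check.
.run_stage <- function(values, targets, orders, iters, tol) {
  residuals <- numeric(iters)
  min_res <- Inf
  for (it in seq_len(iters)) {
    values <- .project_modulus_vec(values, targets, orders)
    values <- project_positive(values, tol)
    res <- .modulus_residual(values, targets, orders)
    residuals[it] <- res
    min_res <- min(min_res, res)
    if (res > 10 * min_res && min_res > 0) {
      abort(sprintf("phasing diverged at iteration %d (residual %.3g, min %.3g).",
                    it, res, min_res),
            class = "glycofibril_divergence_error")
    }
  }
  list(values = values, residuals = residuals)
}

.check_tail_monotone <- function(residuals, label) {
  k <- max(2, ceiling(0.1 * length(residuals)))
  tail_res <- tail(residuals, k)
  if (any(diff(tail_res) > 1e-12 + 1e-6 * abs(tail_res[-k]))) {
    warn(paste0("modulus residual not non-increasing over the last 10% of ",
                label, " iterations."))
  }
}

#' Coupled first-stage phasing of the native and glycated densities
#'
#' Runs `stage1_iters` alternating projections (modulus, then positivity) on
#' two trial densities simultaneously, one constrained by the native moduli
#' and one by the glycated moduli. For the first
#' `floor(averaging_fraction * stage1_iters)` iterations the two trials are
#' replaced by their average after each projection pair; afterwards they
#' evolve independently.
#'
#' @param moduli_ini,moduli_fin Non-negative measured moduli of the native and
#'   glycated states, one per measured order.
#' @param config A [phasing_config()].
#' @param start_ini,start_fin Optional starting profiles (default
#'   [step_start()]).
#' @param grid_size Grid points per period when starts are defaulted.
#' @param d_M Period in nm (metadata).
#' @return List with `rho_ini`, `rho_fin` (`axial_profile`s) and a tibble
#'   `residuals` of per-iteration modulus residuals.
#' @export
stage1_couple <- function(moduli_ini, moduli_fin, config = phasing_config(),
                          start_ini = NULL, start_fin = NULL,
                          grid_size = 1930, d_M = 65.5) {
  orders <- config$measured_orders
  stopifnot(length(moduli_ini) == length(orders),
            length(moduli_fin) == length(orders))
  ri <- .profile_values(start_ini %||% step_start(grid_size, d_M))
  rf <- .profile_values(start_fin %||% step_start(grid_size, d_M))
  stopifnot(length(ri) == length(rf))
  iters <- config$stage1_iters
  n_avg <- floor(config$averaging_fraction * iters)
  res_i <- numeric(iters); res_f <- numeric(iters)
  min_i <- Inf; min_f <- Inf
  for (it in seq_len(iters)) {
    ri <- project_positive(.project_modulus_vec(ri, moduli_ini, orders),
                           config$positivity_tol)
    rf <- project_positive(.project_modulus_vec(rf, moduli_fin, orders),
                           config$positivity_tol)
    if (it <= n_avg) {
      m <- (ri + rf) / 2
      ri <- m; rf <- m
    }
    res_i[it] <- .modulus_residual(ri, moduli_ini, orders)
    res_f[it] <- .modulus_residual(rf, moduli_fin, orders)
    min_i <- min(min_i, res_i[it]); min_f <- min(min_f, res_f[it])
    if ((res_i[it] > 10 * min_i && min_i > 0) ||
        (res_f[it] > 10 * min_f && min_f > 0)) {
      abort(sprintf("stage-1 phasing diverged at iteration %d.", it),
            class = "glycofibril_divergence_error")
    }
  }
  .check_tail_monotone(res_i, "stage-1 (native)")
  .check_tail_monotone(res_f, "stage-1 (glycated)")
  list(
    rho_ini = axial_profile(ri, d_M = d_M, role = "rho_ini"),
    rho_fin = axial_profile(rf, d_M = d_M, role = "rho_fin"),
    residuals = tibble(iteration = seq_len(iters),
                       residual_ini = res_i, residual_fin = res_f)
  )
}

#' Second-stage Fourier-difference phasing
#'
#' Refines an estimate of the glycation density by alternating projections
#' with the Fourier-space targets set to the absolute differences of the
#' measured moduli (glycated minus native) and positivity in real space.
#' Difference amplitudes may be negative; their sign is discarded and absorbed
#' into the retrieved phase.
#'
#' @param delta_moduli Differences `|F_fin,n| - |F_ini,n|` per measured order
#'   (may be negative; absolute values are used as targets).
#' @param start Starting profile (`axial_profile` or numeric).
#' @param config A [phasing_config()].
#' @param d_M Period in nm (metadata).
#' @return List with `rho_gl` (an `axial_profile`) and per-iteration
#'   `residuals`.
#' @export
stage2_fourier_difference <- function(delta_moduli, start,
                                      config = phasing_config(), d_M = 65.5) {
  orders <- config$measured_orders
  stopifnot(length(delta_moduli) == length(orders))
  out <- .run_stage(.profile_values(start), abs(delta_moduli), orders,
                    config$stage2_iters, config$positivity_tol)
  .check_tail_monotone(out$residuals, "stage-2")
  list(
    rho_gl = axial_profile(out$values, d_M = d_M, role = "rho_gl"),
    residuals = tibble(iteration = seq_along(out$residuals),
                       residual = out$residuals)
  )
}

#' Full two-stage phasing refinement
#'
#' Runs `outer_cycles` refinement cycles. Each cycle: (i) coupled stage-1
#' phasing of the native and glycated densities (cycle 1 seeded with the
#' step-function start, later cycles with the previous native solution and
#' native + glycation estimates); (ii) a glycation estimate as the positive
#' part of the difference of the stage-1 solutions; (iii) stage-2
#' Fourier-difference phasing from that estimate. Both moduli sets are first
#' rescaled so the native order-1 modulus is 1 (the same factor applied to
#' the glycated set), which puts the imposed modulation on the scale of the
#' step start so the positivity constraint is active.
#'
#' @param moduli_ini,moduli_fin Measured moduli per measured order, native and
#'   glycated.
#' @param config A [phasing_config()].
#' @param grid_size Grid points per period.
#' @param d_M Period in nm; the achieved resolution `d_M / n_max` is recorded.
#' @return Object of class `phasing_result`: list with `rho_gl`, `rho_ini`,
#'   `rho_fin` (`axial_profile`s), `cycle_log` (per-cycle final residuals),
#'   `resolution_nm`, `config`.
#' @export
phase_refine <- function(moduli_ini, moduli_fin, config = phasing_config(),
                         grid_size = 1930, d_M = 65.5) {
  orders <- config$measured_orders
  stopifnot(length(moduli_ini) == length(orders),
            length(moduli_fin) == length(orders),
            all(moduli_ini >= 0), all(moduli_fin >= 0))
  if (moduli_ini[1] <= 0) {
    abort("the first native modulus must be positive (used for rescaling).",
          class = "glycofibril_domain_error")
  }
  scale <- 1 / moduli_ini[1]
  m_ini <- moduli_ini * scale
  m_fin <- moduli_fin * scale
  delta <- m_fin - m_ini

  start_ini <- NULL; start_fin <- NULL
  cycle_rows <- vector("list", config$outer_cycles)
  s1 <- NULL; s2 <- NULL
  for (cyc in seq_len(config$outer_cycles)) {
    s1 <- stage1_couple(m_ini, m_fin, config,
                        start_ini = start_ini, start_fin = start_fin,
                        grid_size = grid_size, d_M = d_M)
    rg0 <- pmax(s1$rho_fin$value - s1$rho_ini$value, 0)
    s2 <- stage2_fourier_difference(delta, rg0, config, d_M = d_M)
    start_ini <- s1$rho_ini
    start_fin <- axial_profile(s1$rho_ini$value + s2$rho_gl$value,
                               d_M = d_M, role = "rho_fin")
    cycle_rows[[cyc]] <- tibble(
      cycle = cyc,
      residual_ini = tail(s1$residuals$residual_ini, 1),
      residual_fin = tail(s1$residuals$residual_fin, 1),
      residual_diff = tail(s2$residuals$residual, 1)
    )
  }
  structure(
    list(
      rho_gl = s2$rho_gl,
      rho_ini = s1$rho_ini,
      rho_fin = s1$rho_fin,
      cycle_log = bind_rows(cycle_rows),
      resolution_nm = d_M / max(orders),
      config = config
    ),
    class = "phasing_result"
  )
}

#' @export
print.phasing_result <- function(x, ...) {
  cat("<phasing_result>\n")
  cat(sprintf("  %d outer cycles, %d measured orders, resolution %.2f nm\n",
              nrow(x$cycle_log), length(x$config$measured_orders),
              x$resolution_nm))
  cat(sprintf("  final modulus residuals: ini %.3g, fin %.3g, diff %.3g\n",
              tail(x$cycle_log$residual_ini, 1),
              tail(x$cycle_log$residual_fin, 1),
              tail(x$cycle_log$residual_diff, 1)))
  invisible(x)
}

#' @method tidy phasing_result
#' @export
tidy.phasing_result <- function(x, ...) x$cycle_log

#' @method glance phasing_result
#' @export
glance.phasing_result <- function(x, ...) {
  tibble(
    cycles = nrow(x$cycle_log),
    n_orders = length(x$config$measured_orders),
    resolution_nm = x$resolution_nm,
    residual_ini = tail(x$cycle_log$residual_ini, 1),
    residual_fin = tail(x$cycle_log$residual_fin, 1),
    residual_diff = tail(x$cycle_log$residual_diff, 1)
  )
}

#' Best correlation over cyclic shift and mirror inversion
#'
#' Phase retrieval from Fourier moduli determines a profile only up to a
#' cyclic shift and a mirror inversion. This evaluation helper searches both
#' exhaustively (all shifts via FFT cross-correlation, both orientations) and
#' returns the maximal Pearson correlation.
#'
#' @param a,b `axial_profile`s or numeric vectors on grids of equal length.
#' @return Maximum Pearson correlation over all alignments.
#' @export
align_correlation <- function(a, b) {
  av <- .profile_values(a); bv <- .profile_values(b)
  stopifnot(length(av) == length(bv))
  ca <- av - mean(av)
  na <- sqrt(sum(ca^2))
  best <- -1
  for (bb in list(bv, rev(bv))) {
    cb <- bb - mean(bb)
    nb <- sqrt(sum(cb^2))
    if (na == 0 || nb == 0) {
      abort("zero-variance input.", class = "glycofibril_domain_error")
    }
    cc <- Re(fft(fft(ca) * Conj(fft(cb)), inverse = TRUE)) / length(ca)
    best <- max(best, max(cc) / (na * nb))
  }
  best
}

#' Resample an axial profile onto a new grid by periodic linear interpolation
#'
#' @param profile An `axial_profile`.
#' @param grid_size Target number of grid points.
#' @return An `axial_profile` on the new grid.
#' @export
resample_profile <- function(profile, grid_size) {
  stopifnot(inherits(profile, "axial_profile"))
  x <- profile$x_frac; v <- profile$value
  # wrap one point for periodic interpolation
  xx <- c(x, 1)
  vv <- c(v, v[1])
  new_x <- (seq_len(grid_size) - 1) / grid_size
  out <- approx(xx, vv, xout = new_x)$y
  axial_profile(out, d_M = attr(profile, "d_M"),
                role = attr(profile, "role"))
}

#' Write / read an axial profile as CSV
#'
#' @param profile An `axial_profile`.
#' @param path CSV path with columns `fractional_coordinate,value`.
#' @return `path` (writer) or an `axial_profile` (reader).
#' @export
write_axial_profile <- function(profile, path) {
  stopifnot(inherits(profile, "axial_profile"))
  readr::write_csv(
    tibble(fractional_coordinate = profile$x_frac, value = profile$value),
    path
  )
  invisible(path)
}

#' @rdname write_axial_profile
#' @param d_M,role Metadata for the reader.
#' @export
read_axial_profile <- function(path, d_M = 65.5, role = "rho_gl") {
  raw <- readr::read_csv(path, show_col_types = FALSE)
  axial_profile(raw$value, d_M = d_M, role = role)
}
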