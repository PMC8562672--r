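# Gaussian peak on a q grid, for WAXS-style single-peak fixtures.
gaussian_peak <- function(q, q0, height = 1, width = 0.05) {
  height * exp(-0.5 * ((q - q0) / width)^2)
}

test_that("profile construction validates its inputs", {
  q <- seq(0.1, 2, length.out = 50)
  expect_s3_class(saxs_profile(q, q), "saxs_profile")
  expect_error(saxs_profile(q[1:10], q[1:10]),
               class = "glycofibril_format_error")
  expect_error(saxs_profile(rev(q), q), class = "glycofibril_format_error")
  expect_error(saxs_profile(q, q - 1), class = "glycofibril_format_error")
  expect_error(saxs_profile(q, q[1:20]), class = "glycofibril_format_error")
})

test_that("profile files round trip, honour unit headers, and reject junk", {
  q <- seq(0.05, 1.6, by = 0.01)
  prof <- saxs_profile(q, 1 / q^2, label = "bg")
  path <- withr::local_tempfile(fileext = ".dat")
  write_saxs_profile(prof, path)
  back <- read_saxs_profile(path)
  expect_equal(back$q, prof$q, tolerance = 1e-7)
  expect_equal(back$intensity, prof$intensity, tolerance = 1e-7)

  # Angstrom^-1 header: q multiplied by 10
  pa <- withr::local_tempfile(fileext = ".dat")
  writeLines(c("# units: A^-1",
               sprintf("%.6f %.6f", q / 10, 1 / q^2)), pa)
  back_a <- read_saxs_profile(pa)
  expect_equal(back_a$q, q, tolerance = 1e-5)

  empty <- withr::local_tempfile(fileext = ".dat")
  writeLines("# nothing here", empty)
  expect_error(read_saxs_profile(empty), class = "glycofibril_format_error")
})

test_that("meridional indexing recovers the period from synthetic profiles", {
  for (d_M in c(65.5, 64.4)) {
    sc <- synthetic_scenario(seed = 1, lattice = collagen_lattice(d_M = d_M),
                             noise_snr = Inf)
    dens <- gen_density_pair(sc)
    prof <- gen_saxs_profile(dens$rho_ini, sc)
    pk <- index_meridional_peaks(prof, 65, 15)
    expect_equal(attr(pk, "d_M"), d_M, tolerance = 0.1 / d_M)
    expect_identical(nrow(pk), 15L)
  }
})

test_that("relative amplitudes survive indexing on a clean profile", {
  sc <- synthetic_scenario(seed = 2, noise_snr = Inf)
  dens <- gen_density_pair(sc)
  pk <- index_meridional_peaks(gen_saxs_profile(dens$rho_ini, sc), 65, 15)
  truth <- density_moduli(dens$rho_ini)
  ratio <- (pk$amplitude / pk$amplitude[1]) / (truth[pk$order] / truth[1])
  expect_true(all(abs(ratio - 1) < 0.03))
})

test_that("the period estimate ignores intensity scale and a global 1/q^2 term", {
  sc <- synthetic_scenario(seed = 3, noise_snr = Inf, background_amp = 0)
  dens <- gen_density_pair(sc)
  prof <- gen_saxs_profile(dens$rho_ini, sc)
  base <- attr(index_meridional_peaks(prof, 65, 15), "d_M")

  scaled <- saxs_profile(prof$q, prof$intensity * 137)
  expect_equal(attr(index_meridional_peaks(scaled, 65, 15), "d_M"), base,
               tolerance = 1e-6)

  with_bg <- saxs_profile(prof$q, prof$intensity + 5e-4 / prof$q^2)
  expect_equal(attr(index_meridional_peaks(with_bg, 65, 15), "d_M"), base,
               tolerance = 1e-3)
})

test_that("indexing fails cleanly when peaks cannot be located", {
  q <- seq(0.05, 1.6, by = 0.01)
  flat <- saxs_profile(q, rep(1, length(q)))
  expect_error(index_meridional_peaks(flat, 65, 15),
               class = "glycofibril_indexing_error")
  expect_error(index_meridional_peaks(flat, 65, 2),
               class = "glycofibril_domain_error")
})

test_that("equatorial spacing comes from the refined WAXS peak position", {
  q <- seq(3.0, 5.0, by = 0.005)
  for (d_E in c(1.51, 1.69)) {
    q0 <- 2 * pi / d_E
    prof <- saxs_profile(q, gaussian_peak(q, q0) + 0.1, kind = "WAXS")
    expect_equal(fit_d_E(prof), d_E, tolerance = 1e-3)
  }
  flat <- saxs_profile(q, rep(1, length(q)), kind = "WAXS")
  expect_error(fit_d_E(flat), class = "glycofibril_indexing_error")
})

two_level_peaks <- function(sigma, orders = 1:15, noise = 0, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  a <- abs(sin(pi * orders * sigma)) / (pi * orders)
  a <- pmax(a * (1 + rnorm(length(orders), 0, noise)), 0)
  structure(
    tibble::tibble(order = orders, q_center = 2 * pi * orders / 65,
                   amplitude = a),
    class = c("saxs_peaks", "tbl_df", "tbl", "data.frame"),
    d_M = 65, n_max = max(orders)
  )
}

test_that("two-level model fit recovers the overlap fraction", {
  # exact amplitudes
  fit <- fit_two_level_model(two_level_peaks(0.475))
  expect_equal(fit$sigma, 0.475, tolerance = 0.005 / 0.475)
  # 5% amplitude noise, sigma = 0.4: within 0.01
  fit_n <- fit_two_level_model(two_level_peaks(0.4, noise = 0.05, seed = 42))
  expect_lt(abs(fit_n$sigma - 0.4), 0.01)
  # sigma = 0.5 kills the even orders
  a_half <- abs(sin(pi * (1:15) * 0.5)) / (pi * (1:15))
  expect_true(all(a_half[c(2, 4, 6, 8, 10, 12, 14)] < 1e-15))
  # sigma / 1 - sigma ambiguity resolved to <= 0.5
  fit_m <- fit_two_level_model(two_level_peaks(0.6))
  expect_equal(fit_m$sigma, 0.4, tolerance = 0.01)
  expect_lte(fit_m$sigma, 0.5)
})

test_that("peak sets round trip through CSV and expose ordered moduli", {
  pk <- two_level_peaks(0.475)
  path <- withr::local_tempfile(fileext = ".csv")
  write_peaks(pk, path)
  back <- read_peaks(path)
  expect_equal(back$amplitude, pk$amplitude, tolerance = 1e-12)
  expect_equal(attr(back, "d_M"), 65, tolerance = 1e-9)
  m <- peak_moduli(back, 1:15)
  expect_named(m, as.character(1:15))
  expect_error(peak_moduli(back, 1:20), class = "glycofibril_lookup_error")
})
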