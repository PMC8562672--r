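ribose <- get_sugar("ribose")
glucose <- get_sugar("glucose")

test_that("electron counting follows the worked chain", {
  expect_equal(electrons_from_contrast(0.012), 1920)
  expect_equal(electrons_from_contrast(0), 0)
  expect_equal(electrons_from_contrast(0.002), 320)
  expect_error(electrons_from_contrast(1.2), class = "glycofibril_domain_error")
  expect_identical(rough_molecule_count(1920, ribose)$rounded, 24L)
  expect_identical(rough_molecule_count(0, ribose)$rounded, 0L)
  expect_equal(rough_molecule_count(320, glucose)$molecules, 320 / 96,
               tolerance = 1e-12)
})

test_that("the detailed count applies the geometry correction", {
  cfg <- glycation_config()
  expect_equal(detailed_molecule_count(0.012, ribose, cfg), 36.8,
               tolerance = 1e-9)
  cfg1 <- glycation_config(kappa = 1)
  expect_equal(detailed_molecule_count(0.012, ribose, cfg1),
               rough_molecule_count(electrons_from_contrast(0.012),
                                    ribose)$molecules,
               tolerance = 1e-12)
})

test_that("the repetition-unit sugar count is physical and linear", {
  n40 <- sugar_molecules_in_cell(40, ribose)
  expect_equal(n40, 230, tolerance = 0.01)
  expect_equal(sugar_molecules_in_cell(0, ribose), 0)
  expect_equal(sugar_molecules_in_cell(80, ribose), 2 * n40,
               tolerance = 1e-12)
  expect_error(sugar_molecules_in_cell(-1, ribose),
               class = "glycofibril_domain_error")
})

test_that("the available free-volume fraction starts at w_nat and grows with swelling", {
  expect_equal(available_fraction(1.514, 1.514), 0.255)
  expect_equal(available_fraction(1.695, 1.514),
               1 - (1.514 / 1.695)^2 * 0.745, tolerance = 1e-12)
  expect_equal(available_fraction(1.695, 1.514), 0.406, tolerance = 1e-2)
  expect_equal(available_fraction(1.5, 1.5, w_nat = 0), 0)
  expect_warning(available_fraction(1.4, 1.514))
  expect_equal(suppressWarnings(available_fraction(1.4, 1.514)), 0.255)
})

test_that("the PSA-scaled rate reproduces the published ribose and glucose rates", {
  cfg <- glycation_config(c_rate = 0.069)
  expect_equal(effective_rate(cfg, ribose), 0.064, tolerance = 1e-2)
  r_glc <- effective_rate(cfg, glucose)
  expect_gt(r_glc, 0.01)
  expect_lt(r_glc, 0.053)
  unit <- list(name = "unit", molar_mass = 100, electrons = 50, tpsa = 89)
  expect_equal(effective_rate(cfg, unit), 0.069, tolerance = 1e-12)
  expect_error(effective_rate(glycation_config(), ribose),
               class = "glycofibril_domain_error")
})

test_that("per-site probabilities behave in both functional forms", {
  expect_equal(single_site_probability(0, 0.064, "linear_capped"), 0)
  expect_equal(single_site_probability(1, 0.064, "linear_capped"), 0.064)
  expect_equal(single_site_probability(100, 0.064, "linear_capped"), 1)
  t <- seq(0, 30, by = 0.5)
  for (form in c("linear_capped", "exponential")) {
    p <- single_site_probability(t, 0.1, form)
    expect_true(all(p >= 0 & p <= 1))
    expect_true(all(diff(p) >= 0))
  }
  # small-rate limit: the two forms agree to first order
  expect_equal(single_site_probability(1, 1e-6, "exponential"),
               single_site_probability(1, 1e-6, "linear_capped"),
               tolerance = 1e-5)
})

test_that("total probability matches its closed form and a Monte-Carlo oracle", {
  expect_equal(total_probability(0.5, 1), 0.5)
  expect_equal(total_probability(0.5, 2), 0.75)
  expect_equal(total_probability(0.1, 0), 0)
  # Monte-Carlo oracle: n_s independent Bernoulli sugars, 1e6 draws
  set.seed(99)
  for (case in list(c(p = 0.3, n = 7), c(p = 0.05, n = 3))) {
    draws <- matrix(runif(1e6 * case["n"]) < case["p"], ncol = case["n"])
    mc <- mean(rowSums(draws) > 0)
    expect_equal(total_probability(case["p"], case["n"]), mc,
                 tolerance = 3 * sqrt(mc * (1 - mc) / 1e6) / mc,
                 ignore_attr = TRUE)
  }
})

test_that("glycation counts scale with the pair inventory", {
  expect_equal(n_glycations(1, 86), 86)
  expect_equal(n_glycations(0, 86), 0)
  expect_equal(n_glycations(36.8 / 86, 86), 36.8, tolerance = 1e-12)
})

test_that("calibration inverts prediction exactly", {
  cfg <- glycation_config(c_rate = 0.05)
  pred <- predict_glycation(cfg, "ribose", 40, t_years = 90 / 365)
  cfg2 <- glycation_config()
  c_back <- calibrate_c(pred$n_glyc[1], 90 / 365, ribose, 40, cfg2)
  expect_equal(as.numeric(c_back), 0.05, tolerance = 1e-8)
  expect_error(calibrate_c(90, 1, ribose, 40, cfg2),
               class = "glycofibril_domain_error")
})

test_that("calibration on the 90-day ribose count gives a positive rate near the literature scale", {
  cfg <- glycation_config()
  c_hat <- calibrate_c(36.8, 90 / 365, ribose, 40, cfg)
  expect_gt(as.numeric(c_hat), 0)
  # same order of magnitude as the literature reference accumulation rate
  expect_lt(abs(log10(as.numeric(c_hat) / cfg$r_age_reference)), 1)
})

test_that("doubling the sugar pool halves the calibrated rate-time product at small P", {
  cfg <- glycation_config()
  target <- 2; t_obs <- 0.25
  c1 <- as.numeric(calibrate_c(target, t_obs, ribose, 10, cfg))
  c2 <- as.numeric(calibrate_c(target, t_obs, ribose, 20, cfg))
  expect_equal(c1 / c2, 2, tolerance = 0.02)
})

test_that("prediction curves are monotone, bounded, and ordered by sugar", {
  cfg <- glycation_config(c_rate = 0.0411)
  t <- seq(0, 10, by = 0.1)
  rb <- predict_glycation(cfg, "ribose", 40, t)
  gl <- predict_glycation(cfg, "glucose", 40, t)
  for (pred in list(rb, gl)) {
    expect_true(all(diff(pred$fraction) >= 0))
    expect_true(all(pred$fraction >= 0 & pred$fraction <= 1))
    expect_true(all(pred$n_glyc <= cfg$n_pairs))
    expect_equal(pred$fraction[1], 0)
  }
  expect_true(all(rb$fraction >= gl$fraction))
  flat <- predict_glycation(cfg, "ribose", 0, t)
  expect_true(all(flat$fraction == 0))
})

test_that("volume curves rise to their saturation increments", {
  cfg <- glycation_config(c_rate = 0.0411)
  vc_rb <- volume_curve(cfg, "ribose", 40, 0.36, t_years = c(0, 1, 500))
  expect_equal(vc_rb$delta_v[1], 0)
  expect_equal(vc_rb$delta_v[3], 0.36, tolerance = 1e-6)
  vc_gl <- volume_curve(cfg, "glucose", 40, 0.10, t_years = c(0, 2000))
  expect_equal(vc_gl$delta_v[2], 0.10, tolerance = 1e-6)
  expect_true(all(diff(vc_rb$delta_v) >= 0))
})
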