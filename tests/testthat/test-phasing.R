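gaussian_profile <- function(sites, grid = 1930) {
  x <- (seq_len(grid) - 1) / grid
  v <- rep(0, grid)
  for (i in seq_len(nrow(sites))) {
    d <- ((x - sites$x[i] + 0.5) %% 1) - 0.5
    v <- v + sites$a[i] * exp(-0.5 * (d / sites$w[i])^2)
  }
  v
}

test_that("the step start is half ones, half zeros", {
  expect_identical(step_start(4)$value, c(1, 1, 0, 0))
  s <- step_start(1930)
  expect_identical(sum(s$value == 1), 965L)
  expect_identical(mean(s$value), 0.5)
  expect_error(step_start(2), class = "glycofibril_domain_error")
})

test_that("the modulus projector fixes measured orders and nothing else", {
  grid <- 64
  x <- (seq_len(grid) - 1) / grid
  prof <- 1 + 0.5 * cos(2 * pi * x) + 0.2 * cos(2 * pi * 5 * x)
  m <- density_moduli(prof, 1:3)
  # already satisfying targets: fixed point
  same <- project_modulus(prof, m, 1:3)
  expect_equal(same, prof, tolerance = 1e-12)
  # doubling the order-1 target doubles that mode, phase preserved
  doubled <- project_modulus(prof, m * c(2, 1, 1), 1:3)
  expect_equal(doubled, 1 + 1.0 * cos(2 * pi * x) + 0.2 * cos(2 * pi * 5 * x),
               tolerance = 1e-10)
  # projector property: residual zero on measured orders afterwards
  tgt <- c(0.3, 0.1, 0.05)
  proj <- project_modulus(prof, tgt, 1:3)
  expect_equal(unname(density_moduli(proj, 1:3)), tgt, tolerance = 1e-12)
  # unmeasured order 5 untouched
  expect_equal(unname(density_moduli(proj, 5)), 0.1, tolerance = 1e-12)
  expect_error(project_modulus(prof, rep(1, 40), 1:40),
               class = "glycofibril_domain_error")
})

test_that("the positivity projector clips at zero and is idempotent", {
  expect_identical(project_positive(c(-1, 2)), c(0, 2))
  v <- c(0.5, 1.2, 3)
  expect_identical(project_positive(v), v)
  set.seed(1)
  r <- rnorm(100)
  expect_identical(project_positive(project_positive(r)), project_positive(r))
})

test_that("coupled stage 1 respects symmetry and degenerate inputs", {
  cfg <- phasing_config(stage1_iters = 50, measured_orders = 1:15)
  sc <- synthetic_scenario(seed = 1)
  dens <- gen_density_pair(sc, grid_size = 256)
  m <- density_moduli(dens$rho_ini, 1:15)
  m <- m / m[1]
  # identical moduli and starts: the two trials stay identical
  out <- stage1_couple(m, m, cfg, grid_size = 256)
  expect_equal(out$rho_ini$value, out$rho_fin$value, tolerance = 1e-12)
  # zero targets on every nonzero order: only the mean survives
  grid <- 64
  cfg0 <- phasing_config(stage1_iters = 10, measured_orders = 1:31)
  out0 <- stage1_couple(rep(0, 31), rep(0, 31), cfg0, grid_size = grid)
  expect_equal(out0$rho_ini$value, rep(0.5, grid), tolerance = 1e-10)
})

test_that("stage 1 retrieves the two-level native density from its moduli", {
  sc <- synthetic_scenario(seed = 1)
  dens <- gen_density_pair(sc)
  m_ini <- density_moduli(dens$rho_ini)
  m_fin <- density_moduli(dens$rho_fin)
  scale <- 1 / m_ini[1]
  out <- stage1_couple(m_ini * scale, m_fin * scale, phasing_config())
  expect_gt(align_correlation(dens$rho_ini, out$rho_ini), 0.85)
})

test_that("stage 2 refines a resolution-degraded glycation estimate", {
  truth <- gaussian_profile(data.frame(x = c(0.25, 0.7), a = c(0.05, 0.04),
                                       w = c(0.03, 0.025)))
  dm <- density_moduli(truth)
  # zero difference moduli with a null starting estimate: nothing appears
  z <- stage2_fourier_difference(rep(0, 15), rep(0, 1930),
                                 phasing_config(stage2_iters = 20))
  expect_lt(max(z$rho_gl$value), 1e-12)
  # start: truth smoothed far below the measurement resolution
  box <- rep(1 / 193, 193)
  padded <- c(tail(truth, 96), truth, head(truth, 96))
  start <- as.numeric(stats::filter(padded, box, sides = 2)[97:(96 + 1930)])
  out <- stage2_fourier_difference(dm, start, phasing_config())
  expect_gt(align_correlation(truth, out$rho_gl$value), 0.9)
  # modulus constraint satisfied at convergence
  got <- unname(density_moduli(out$rho_gl$value))
  expect_lt(max(abs(got - unname(dm)) / unname(dm)), 1e-6)
})

test_that("full refinement recovers a planted glycation profile", {
  sc <- synthetic_scenario(seed = 1)
  dens <- gen_density_pair(sc)
  m_ini <- density_moduli(dens$rho_ini)
  m_fin <- density_moduli(dens$rho_fin)
  res <- phase_refine(m_ini, m_fin)
  expect_equal(res$resolution_nm, 65.5 / 15, tolerance = 1e-12)
  expect_gt(align_correlation(dens$rho_gl, res$rho_gl), 0.85)
  # identical inputs: near-zero retrieved density
  null <- phase_refine(m_ini, m_ini, phasing_config(outer_cycles = 1))
  expect_lt(max(null$rho_gl$value), 1e-6 * max(dens$rho_ini$value))
})

test_that("refinement is deterministic and stable across grid sizes", {
  sc <- synthetic_scenario(seed = 5)
  dens <- gen_density_pair(sc)
  m_ini <- density_moduli(dens$rho_ini)
  m_fin <- density_moduli(dens$rho_fin)
  cfg <- phasing_config(outer_cycles = 2)
  a <- phase_refine(m_ini, m_fin, cfg)
  b <- phase_refine(m_ini, m_fin, cfg)
  expect_identical(a$rho_gl$value, b$rho_gl$value)
  for (grid in c(960, 3860)) {
    truth <- gen_density_pair(sc, grid_size = grid)$rho_gl
    res <- phase_refine(m_ini, m_fin, phasing_config(), grid_size = grid)
    expect_gt(align_correlation(truth, res$rho_gl), 0.8)
  }
})

test_that("alignment correlation is exhaustive over shift and mirror", {
  set.seed(7)
  v <- gaussian_profile(data.frame(x = c(0.2, 0.55), a = c(1, 0.6),
                                   w = c(0.02, 0.04)), grid = 500)
  shifted <- c(tail(v, 100), head(v, 400))
  expect_equal(align_correlation(v, shifted), 1, tolerance = 1e-9)
  expect_equal(align_correlation(v, rev(shifted)), 1, tolerance = 1e-9)
  expect_error(align_correlation(v, rep(1, 500)),
               class = "glycofibril_domain_error")
})

test_that("axial profiles resample periodically and round trip via CSV", {
  v <- gaussian_profile(data.frame(x = 0.3, a = 1, w = 0.05), grid = 400)
  prof <- axial_profile(v, role = "rho_gl")
  up <- resample_profile(prof, 800)
  expect_equal(align_correlation(up, resample_profile(up, 800)), 1,
               tolerance = 1e-12)
  expect_equal(max(up$value), max(v), tolerance = 1e-3)
  path <- withr::local_tempfile(fileext = ".csv")
  write_axial_profile(prof, path)
  back <- read_axial_profile(path)
  expect_equal(back$value, prof$value, tolerance = 1e-12)
})
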