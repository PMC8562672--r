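test_that("residue tables validate coordinates and classes", {
  expect_error(residue_table(integer(0), numeric(0), character(0)),
               class = "glycofibril_format_error")
  expect_error(residue_table(0, 1.0, "ARG"),
               class = "glycofibril_domain_error")
  expect_error(residue_table(0, 0.5, "GLY"),
               class = "glycofibril_domain_error")
  tab <- residue_table(c(0, 1), c(0.2, 0.7), c("ARG", "LYS_HYL"))
  path <- withr::local_tempfile(fileext = ".csv")
  write_residue_table(tab, path)
  expect_equal(read_residue_table(path)$x_frac, tab$x_frac)
})

test_that("rasterization puts exactly one unit of mass per residue", {
  lat <- collagen_lattice()
  tab <- residue_table(c(0, 2, 4), c(0.1, 0.5, 0.9),
                       c("ARG", "ARG", "LYS_HYL"))
  ras <- rasterize_residues(tab, lat)
  expect_equal(sum(ras$map_arg), 2, tolerance = 1e-12)
  expect_equal(sum(ras$map_lys), 1, tolerance = 1e-12)
  # wrap: a residue at the right edge keeps unit mass via periodic x
  edge <- rasterize_residues(residue_table(0, 0.999, "ARG"), lat)
  expect_equal(sum(edge$map_arg), 1, tolerance = 1e-12)
  expect_gt(sum(edge$map_arg[, 1:3]), 0)
  # strand rows sit d_E / d_M * x_pixels apart
  expect_equal(ras$geometry$row_spacing, 1.514 / 65.5 * 1930,
               tolerance = 1e-9)
  expect_error(rasterize_residues(residue_table(7, 0.5, "ARG"), lat),
               class = "glycofibril_domain_error")
})

test_that("disk blur conserves mass and spreads an impulse into a disk", {
  lat <- collagen_lattice()
  m <- matrix(0, 300, 400)
  m[150, 200] <- 1
  b <- disk_blur(m, 4.3, lat, x_pixels = 1930)
  expect_equal(sum(b), 1, tolerance = 1e-9)
  # impulse response: a flat disk (all nonzero values equal)
  nz <- b[b > 1e-12]
  expect_lt(diff(range(nz)) / mean(nz), 1e-6)
  # expected diameter ~ 4.3 / 65.5 * 1930 = 127 px
  expect_equal(sum(abs(b[150, ]) > 1e-12), 127, tolerance = 0)
  expect_error(disk_blur(matrix(0, 5, 5), 4.3, lat, x_pixels = 1930),
               class = "glycofibril_domain_error")
})

test_that("the proximity product peaks only where both classes meet", {
  lat <- collagen_lattice()
  co <- residue_table(c(1, 1), c(0.3, 0.3), c("ARG", "LYS_HYL"))
  ras <- rasterize_residues(co, lat)
  D <- proximity_map(ras$map_arg, ras$map_lys, 4.3, lat)
  peak_col <- which.max(apply(D, 2, max))
  expect_equal(peak_col / 1930, 0.3, tolerance = 0.01)
  # commutative in its two maps
  D2 <- proximity_map(ras$map_lys, ras$map_arg, 4.3, lat)
  expect_equal(D, D2, tolerance = 1e-12)
  # residues far apart: identically (numerically) zero product
  far <- residue_table(c(1, 1), c(0.1, 0.6), c("ARG", "LYS_HYL"))
  ras_f <- rasterize_residues(far, lat)
  Df <- proximity_map(ras_f$map_arg, ras_f$map_lys, 4.3, lat)
  expect_lt(max(Df), 1e-12 * max(D))
  expect_error(proximity_map(ras$map_arg, matrix(0, 2, 2), 4.3, lat),
               class = "glycofibril_domain_error")
})

test_that("axial projection preserves mass and shape", {
  lat <- collagen_lattice()
  m <- matrix(1, 10, 200)
  prof <- project_axial(m, lat)
  expect_true(all(prof$value == 10))
  expect_equal(sum(prof$value), sum(m))
  m2 <- matrix(0, 10, 200)
  m2[4, 57] <- 3
  prof2 <- project_axial(m2, lat)
  expect_identical(which.max(prof2$value), 57L)
})

test_that("profile correlation is exact on self, sign-flips on negation, and ignores affine scale", {
  set.seed(3)
  v <- cumsum(rnorm(400))
  a <- axial_profile(v - min(v) + 0.1, role = "rho_model")
  expect_equal(correlate_profiles(a, a)$r, 1)
  neg <- axial_profile(-(v - min(v) + 0.1) + 10, role = "rho_gl")
  expect_equal(correlate_profiles(a, neg)$r, -1)
  scaled <- axial_profile(3.7 * (v - min(v) + 0.1) + 2, role = "rho_gl")
  expect_equal(correlate_profiles(a, scaled)$r, 1, tolerance = 1e-12)
  flat <- axial_profile(rep(1, 400), role = "rho_gl")
  expect_error(correlate_profiles(a, flat),
               class = "glycofibril_domain_error")
})

test_that("the whole chain is equivariant under a cyclic shift of the table", {
  lat <- collagen_lattice()
  base <- residue_table(c(0, 0, 3, 3), c(0.2, 0.21, 0.6, 0.61),
                        c("ARG", "LYS_HYL", "ARG", "LYS_HYL"))
  shift_px <- 400                      # integer pixels, so the shift is exact
  shift <- shift_px / 1930
  moved <- residue_table(base$strand_row, (base$x_frac + shift) %% 1,
                         base$residue_class)
  run <- function(tab) {
    ras <- rasterize_residues(tab, lat)
    project_axial(proximity_map(ras$map_arg, ras$map_lys, 4.3, lat), lat)
  }
  p1 <- run(base)$value
  p2 <- run(moved)$value
  shifted_p1 <- c(tail(p1, shift_px), head(p1, 1930 - shift_px))
  expect_equal(p2, shifted_p1, tolerance = 1e-6 * max(p1))
})
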