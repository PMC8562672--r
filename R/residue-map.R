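# Linearized 2D residue map of the staggered repetition unit. Arginine and
# lysine/hydroxylysine positions are drawn as small disks on a raster whose
# pixel size is the same along the axial (D-period, periodic) and lateral
# (equatorial) directions; blurring each class map to the experimental
# resolution and multiplying the two gives a proximity likelihood for
# sugar-mediated crosslink sites, which projects to a 1D axial model profile.

#' Residue position table
#'
#' @param strand_row Integer strand index, `0 .. n_strands - 1`.
#' @param x_frac Fractional axial coordinate of the residue in `[0, 1)`.
#' @param residue_class `"ARG"` or `"LYS_HYL"`.
#' @return A tibble of class `residue_table`.
#' @export
residue_table <- function(strand_row, x_frac, residue_class) {
  if (length(strand_row) == 0) {
    abort("residue table is empty.", class = "glycofibril_format_error")
  }
  if (any(x_frac < 0 | x_frac >= 1)) {
    abort("`x_frac` must lie in [0, 1).", class = "glycofibril_domain_error")
  }
  if (!all(residue_class %in% c("ARG", "LYS_HYL"))) {
    abort("`residue_class` must be 'ARG' or 'LYS_HYL'.",
          class = "glycofibril_domain_error")
  }
  out <- tibble(strand_row = as.integer(strand_row),
                x_frac = as.numeric(x_frac),
                residue_class = residue_class)
  class(out) <- c("residue_table", class(out))
  out
}

#' Read / write a residue table CSV (`strand_row,x_frac,residue_class`)
#'
#' @param path CSV path.
#' @return A `residue_table` tibble.
#' @export
read_residue_table <- function(path) {
  raw <- readr::read_csv(path, show_col_types = FALSE)
  residue_table(raw$strand_row, raw$x_frac, raw$residue_class)
}

#' @rdname read_residue_table
#' @param table A `residue_table`.
#' @export
write_residue_table <- function(table, path) {
  readr::write_csv(as_tibble(table), path)
  invisible(path)
}

# Raster geometry shared by all 2D operations: columns are the periodic axial
# direction (x, x_pixels wide), rows the lateral direction (y). Strand rows
# sit d_E apart in pixels of size d_M / x_pixels, with a margin above and
# below for blur support.
.raster_geometry <- function(lattice, x_pixels, margin_px) {
  px_nm <- lattice$d_M / x_pixels
  row_spacing <- lattice$d_E / px_nm
  height <- ceiling((lattice$n_strands - 1) * row_spacing) + 1 + 2 * margin_px
  list(px_nm = px_nm, row_spacing = row_spacing, height = height,
       margin = margin_px)
}

# Unit-mass disk stamp: all raster pixels within radius_px of the centre get
# equal weight summing to 1; periodic wrap in x, plain clipping in y.
.stamp_disk <- function(raster, cx, cy, radius_px) {
  r <- max(0L, as.integer(radius_px))
  offs <- expand.grid(dx = -r:r, dy = -r:r)
  offs <- offs[offs$dx^2 + offs$dy^2 <= r^2 + 1e-9, ]
  w <- 1 / nrow(offs)
  nx <- ncol(raster); ny <- nrow(raster)
  xs <- ((round(cx) + offs$dx - 1) %% nx) + 1
  ys <- round(cy) + offs$dy
  keep <- ys >= 1 & ys <= ny
  idx <- cbind(ys[keep], xs[keep])
  raster[idx] <- raster[idx] + w
  raster
}

#' Rasterize residue positions into per-class occupancy maps
#'
#' Draws each residue as a unit-mass disk of radius `bullet_radius_px` at
#' `(x_frac * x_pixels, strand_row * d_E / d_M * x_pixels + margin)`. The
#' canvas covers all strand rows plus a blur margin; the axial direction
#' wraps periodically.
#'
#' @param table A [residue_table()].
#' @param lattice A [collagen_lattice()].
#' @param x_pixels Axial raster width (pixels per period).
#' @param bullet_radius_px Residue disk radius in pixels.
#' @param margin_px Extra rows above and below the strand block; defaults to
#'   one resolution-disk diameter for the 4.3 nm default resolution.
#' @return Object of class `residue_raster`: list with matrices `map_arg`,
#'   `map_lys` (rows = lateral y, columns = axial x) and the raster geometry.
#' @export
rasterize_residues <- function(table, lattice = collagen_lattice(),
                               x_pixels = 1930, bullet_radius_px = 2,
                               margin_px = NULL) {
  stopifnot(inherits(table, "residue_table"))
  if (nrow(table) == 0) abort("residue table is empty.",
                              class = "glycofibril_format_error")
  if (any(table$strand_row >= lattice$n_strands)) {
    abort("`strand_row` exceeds the lattice strand count.",
          class = "glycofibril_domain_error")
  }
  margin_px <- margin_px %||%
    (2 * ceiling(4.3 / lattice$d_M * x_pixels / 2) + 1)
  geom <- .raster_geometry(lattice, x_pixels, margin_px)
  blank <- matrix(0, nrow = geom$height, ncol = x_pixels)
  maps <- list(ARG = blank, LYS_HYL = blank)
  for (i in seq_len(nrow(table))) {
    cls <- table$residue_class[i]
    cx <- table$x_frac[i] * x_pixels + 1
    cy <- table$strand_row[i] * geom$row_spacing + 1 + geom$margin
    maps[[cls]] <- .stamp_disk(maps[[cls]], cx, cy, bullet_radius_px)
  }
  structure(
    list(map_arg = maps$ARG, map_lys = maps$LYS_HYL,
         x_pixels = x_pixels, lattice = lattice, geometry = geom),
    class = "residue_raster"
  )
}

# FFT convolution of a raster with a kernel, periodic along x (columns),
# zero-padded along y (rows).
.convolve_xperiodic <- function(mat, kernel) {
  ky <- nrow(kernel); kx <- ncol(kernel)
  ny <- nrow(mat); nx <- ncol(mat)
  if (ky > ny || kx > nx) {
    abort("blur disk larger than the canvas.",
          class = "glycofibril_domain_error")
  }
  pad_y <- ny + ky                      # zero padding in y only
  big_m <- matrix(0, pad_y, nx); big_m[1:ny, ] <- mat
  big_k <- matrix(0, pad_y, nx)
  # centre kernel at origin with wraparound
  oy <- (ky - 1) / 2; ox <- (kx - 1) / 2
  for (i in seq_len(ky)) {
    for (j in seq_len(kx)) {
      big_k[((i - 1 - oy) %% pad_y) + 1, ((j - 1 - ox) %% nx) + 1] <- kernel[i, j]
    }
  }
  out <- Re(fft(fft(big_m) * fft(big_k), inverse = TRUE)) / (pad_y * nx)
  out[1:ny, , drop = FALSE]
}

# Uniform disk kernel of the given diameter in pixels (rounded to odd),
# normalized to unit integral.
.disk_kernel <- function(diameter_px) {
  d <- as.integer(diameter_px)
  if (d %% 2 == 0) d <- d + 1L
  r <- (d - 1) / 2
  g <- expand.grid(i = -r:r, j = -r:r)
  k <- matrix(as.numeric(g$i^2 + g$j^2 <= r^2 + 1e-9), d, d)
  k / sum(k)
}

#' Blur a raster with a uniform resolution disk
#'
#' Convolves the map with a uniform circular disk whose diameter equals the
#' experimental resolution expressed in raster pixels
#' (`R_nm / d_M * x_pixels`, rounded to odd). Periodic along the axial
#' direction, zero-padded laterally.
#'
#' @param map A numeric matrix (rows = y, columns = periodic x).
#' @param R_nm Disk diameter in nm (the spatial resolution).
#' @param lattice A [collagen_lattice()] supplying `d_M`.
#' @param x_pixels Axial raster width used to convert nm to pixels.
#' @return Blurred matrix of the same shape.
#' @export
disk_blur <- function(map, R_nm = 4.3, lattice = collagen_lattice(),
                      x_pixels = ncol(map)) {
  if (!(R_nm > 0)) abort("`R_nm` must be positive.",
                         class = "glycofibril_domain_error")
  kernel <- .disk_kernel(R_nm / lattice$d_M * x_pixels)
  .convolve_xperiodic(map, kernel)
}

#' Arginine-lysine proximity map
#'
#' Pointwise product of the resolution-blurred arginine and
#' lysine/hydroxylysine occupancy maps. Maxima mark positions where residues
#' of both classes lie within about one resolution disk of each other - the
#' candidate sugar-crosslink sites.
#'
#' @param map_arg,map_lys Occupancy matrices sharing one geometry (e.g. from
#'   [rasterize_residues()]).
#' @inheritParams disk_blur
#' @return Matrix `D(x, y)` of the same shape.
#' @export
proximity_map <- function(map_arg, map_lys, R_nm = 4.3,
                          lattice = collagen_lattice(),
                          x_pixels = ncol(map_arg)) {
  if (!all(dim(map_arg) == dim(map_lys))) {
    abort("maps do not share geometry.", class = "glycofibril_domain_error")
  }
  disk_blur(map_arg, R_nm, lattice, x_pixels) *
    disk_blur(map_lys, R_nm, lattice, x_pixels)
}

#' Project a 2D map onto the axial coordinate
#'
#' Integrates (sums) the map along the lateral direction, returning a 1D
#' axial model profile.
#'
#' @param map A numeric matrix (rows = y, columns = periodic x).
#' @param lattice A [collagen_lattice()] (metadata).
#' @return An `axial_profile` with role `rho_model`.
#' @export
project_axial <- function(map, lattice = collagen_lattice()) {
  axial_profile(colSums(map), d_M = lattice$d_M, role = "rho_model")
}

#' Correlate a model profile with a retrieved glycation profile
#'
#' Resamples both profiles to a common grid (periodic linear interpolation),
#' computes their Pearson correlation, and returns the pair normalized to a
#' common integral for plotting.
#'
#' @param model,rho_gl `axial_profile`s (any grid sizes).
#' @param grid_size Common grid (default: the finer of the two).
#' @return List with `r` (Pearson correlation) and `profiles` (a long tibble
#'   of the common-integral-normalized pair).
#' @export
correlate_profiles <- function(model, rho_gl, grid_size = NULL) {
  grid_size <- grid_size %||% max(nrow(model), nrow(rho_gl))
  m <- resample_profile(model, grid_size)$value
  g <- resample_profile(rho_gl, grid_size)$value
  if (stats::sd(m) == 0 || stats::sd(g) == 0) {
    abort("zero-variance input.", class = "glycofibril_domain_error")
  }
  r <- stats::cor(m, g)
  # normalize to a common (unit) integral for display
  x <- (seq_len(grid_size) - 1) / grid_size
  norm <- function(v) if (sum(v) != 0) v / (sum(v) / grid_size) else v
  profiles <- bind_rows(
    tibble(x_frac = x, value = norm(m), profile = "model"),
    tibble(x_frac = x, value = norm(g), profile = "rho_gl")
  )
  list(r = r, profiles = profiles)
}
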