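# Staggered-fibril lattice geometry: the Hodge-Petruska style abstraction of
# five laterally packed collagen molecules, each offset axially by one D-period,
# giving alternating overlap (5 molecule fractions) and gap (4 fractions) bands.

# Printed anchors for the in-plane unit cell. The swollen (in-solution) cell
# area is modelled as k * d_E^2, with k calibrated once so that the reference
# equatorial spacing reproduces the 21.9 nm^2 swollen-cell area; the native
# (dry, physiological) cell is 26% smaller.
.swollen_area_ref <- 21.9   # nm^2, swollen in-plane unit cell at reference d_E
.d_E_swollen_ref <- 1.514   # nm, reference equatorial spacing of the swollen cell
.swell_factor <- 1.26       # swollen / native area ratio
.w_nat <- 0.255             # free (inter-molecular) area fraction of native cell

#' Staggered collagen lattice
#'
#' Describes the axial and lateral lattice of a collagen fibril: the meridional
#' D-period `d_M` (~65 nm), the equatorial inter-molecule distance `d_E`
#' (~1.5 nm), and the overlap fraction `sigma` splitting each period into a
#' dense overlap band of width `sigma * d_M` (five molecule fractions) and a
#' gap band of width `(1 - sigma) * d_M` (four fractions plus one gap).
#'
#' @param d_M Meridional period in nm.
#' @param d_E Equatorial centre-to-centre inter-molecule distance in nm.
#' @param sigma Overlap fraction of the period, in (0, 1).
#' @param n_strands Number of laterally staggered molecules per repetition
#'   unit.
#' @param molecule_length Length of one triple-helix molecule in nm.
#' @param residues_per_period Residue count per D-period of one strand; the
#'   axial rise per residue is derived as `d_M / residues_per_period`.
#'
#' @return An object of class `collagen_lattice` (a named list with a derived
#'   `rise_per_residue` field, nm).
#' @examples
#' lat <- collagen_lattice()
#' lat$rise_per_residue # ~0.28 nm
#' @export
collagen_lattice <- function(d_M = 65.5, d_E = 1.514, sigma = 0.475,
                             n_strands = 5, molecule_length = 306,
                             residues_per_period = 233) {
  if (!(d_M > 0) || !(d_E > 0)) {
    abort("`d_M` and `d_E` must be positive.", class = "glycofibril_domain_error")
  }
  if (!(sigma > 0 && sigma < 1)) {
    abort("`sigma` must lie strictly between 0 and 1.",
          class = "glycofibril_domain_error")
  }
  if (n_strands < 2) {
    abort("`n_strands` must be at least 2.", class = "glycofibril_domain_error")
  }
  structure(
    list(
      d_M = d_M, d_E = d_E, sigma = sigma, n_strands = n_strands,
      molecule_length = molecule_length,
      residues_per_period = residues_per_period,
      rise_per_residue = d_M / residues_per_period
    ),
    class = "collagen_lattice"
  )
}

#' @export
print.collagen_lattice <- function(x, ...) {
  cat("<collagen_lattice>\n")
  cat(sprintf("  d_M = %.2f nm, d_E = %.3f nm, sigma = %.3f\n",
              x$d_M, x$d_E, x$sigma))
  cat(sprintf("  %d strands, rise %.3f nm/residue (%d residues/period)\n",
              x$n_strands, x$rise_per_residue, x$residues_per_period))
  invisible(x)
}

#' Residues per D-period of the staggered unit
#'
#' The whole staggered repetition unit holds about 1050 residues shared among
#' an effective 4.5 molecule fractions (average of 5 in the overlap band and 4
#' in the gap band), giving 233 residues per period.
#'
#' @param total_residues Residues in the whole staggered repetition unit.
#' @param effective_strands Effective number of molecule fractions.
#' @return Integer residue count per period.
#' @examples
#' staggered_residue_count() # 233
#' @export
staggered_residue_count <- function(total_residues = 1050,
                                    effective_strands = 4.5) {
  as.integer(round(total_residues / effective_strands))
}

#' Overlap and gap band widths
#'
#' Splits the D-period into the overlap band (`sigma * d_M`) and the gap band
#' (`(1 - sigma) * d_M`); the two always sum to `d_M` exactly.
#'
#' @param lattice A [collagen_lattice()].
#' @return A one-row tibble with `overlap_width` and `gap_width` (nm).
#' @examples
#' band_widths(collagen_lattice(d_M = 65.5, sigma = 0.475))
#' @export
band_widths <- function(lattice) {
  stopifnot(inherits(lattice, "collagen_lattice"))
  tibble(
    overlap_width = lattice$sigma * lattice$d_M,
    gap_width = (1 - lattice$sigma) * lattice$d_M
  )
}

#' In-plane unit-cell area of the staggered unit
#'
#' Area of the in-plane cell holding `n_strands` molecules, modelled as
#' `k * d_E^2` with `k` calibrated so the swollen (in-solution) cell at the
#' reference equatorial spacing has area 21.9 nm^2. The native cell is the
#' swollen one divided by 1.26 (the swollen cell is ~26% larger).
#'
#' @param d_E Equatorial spacing in nm.
#' @param state `"swollen"` (in solution) or `"native"`.
#' @return Area in nm^2.
#' @examples
#' unit_cell_area(1.514, "swollen") # 21.9
#' unit_cell_area(1.514, "native")  # 17.4
#' @export
unit_cell_area <- function(d_E, state = c("swollen", "native")) {
  state <- match.arg(state)
  if (!(d_E > 0)) abort("`d_E` must be positive.", class = "glycofibril_domain_error")
  k <- .swollen_area_ref / .d_E_swollen_ref^2
  area <- k * d_E^2
  if (state == "native") area <- area / .swell_factor
  area
}

#' Free in-plane area fraction between collagen molecules
#'
#' Fraction `w` of the in-plane unit cell not occupied by the (cylindrical)
#' molecule cross-sections: `w = 1 - A_mol / A_cell`. The total molecular
#' cross-section `A_mol` is fixed by requiring `w = 0.255` at the native cell
#' area, so `w` grows as the lattice swells.
#'
#' @param area_cell In-plane cell area, nm^2.
#' @param per_molecule If `TRUE`, divide the fraction equally among the five
#'   molecules of the cell (the per-molecule available-space share).
#' @param n_strands Number of molecules sharing the cell.
#' @return Free-area fraction in (0, 1).
#' @examples
#' packing_free_fraction(unit_cell_area(1.514, "native"))  # 0.255
#' packing_free_fraction(unit_cell_area(1.514, "swollen")) # ~0.41
#' @export
packing_free_fraction <- function(area_cell, per_molecule = FALSE,
                                  n_strands = 5) {
  a_native <- .swollen_area_ref / .swell_factor
  a_mol <- (1 - .w_nat) * a_native
  if (any(area_cell < a_mol)) {
    abort("`area_cell` is smaller than the total molecular cross-section.",
          class = "glycofibril_domain_error")
  }
  w <- 1 - a_mol / area_cell
  if (per_molecule) w <- w / n_strands
  w
}

#' Reference polar surface area of the native packing
#'
#' The effective space between molecules in the native in-plane cell,
#' expressed as an area on the scale of molecular polar surface areas:
#' per-molecule free fraction times native cell area, converted from nm^2
#' to Angstrom^2 and rounded to the nearest integer.
#'
#' @param w_per_molecule Per-molecule free-space fraction (default 0.255 / 5).
#' @param native_area Native unit-cell area in nm^2.
#' @return Integer area in Angstrom^2.
#' @examples
#' psa_nat_estimate(0.051, 17.4) # 89
#' @export
psa_nat_estimate <- function(w_per_molecule = .w_nat / 5,
                             native_area = .swollen_area_ref / .swell_factor) {
  if (!(w_per_molecule > 0) || !(native_area > 0)) {
    abort("inputs must be positive.", class = "glycofibril_domain_error")
  }
  round(w_per_molecule * native_area * 100)
}
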