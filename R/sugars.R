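# Reducing-sugar registry. Molar masses and topological polar surface areas
# (TPSA) are standard compound-database values; electron counts are sums of
# atomic numbers (C5H10O5 -> 80, C6H12O6 -> 96).

#' Sugar registry
#'
#' Loads the registry of reducing sugars used by the kinetics model. Each row
#' holds the molar mass (g/mol), the electron count per molecule, and the
#' topological polar surface area (TPSA, Angstrom^2) that sets the
#' sugar-dependent glycation rate. The packaged defaults cover ribose and
#' glucose; pass a CSV path with the same header to extend or override.
#'
#' @param path Optional CSV file `name,molar_mass,electrons,tpsa`; defaults to
#'   the packaged registry.
#' @return A tibble with columns `name`, `molar_mass`, `electrons`, `tpsa`.
#' @examples
#' sugar_registry()
#' @export
sugar_registry <- function(path = NULL) {
  path <- path %||% system.file("extdata", "sugars.csv", package = "glycofibril")
  reg <- readr::read_csv(path, show_col_types = FALSE,
                         col_types = readr::cols(
                           name = readr::col_character(),
                           molar_mass = readr::col_double(),
                           electrons = readr::col_integer(),
                           tpsa = readr::col_double()
                         ))
  if (!all(c("name", "molar_mass", "electrons", "tpsa") %in% names(reg))) {
    abort("sugar registry needs columns name, molar_mass, electrons, tpsa.",
          class = "glycofibril_format_error")
  }
  bad <- reg$molar_mass <= 0 | reg$electrons <= 0 | reg$tpsa <= 0
  if (any(bad)) {
    abort("sugar registry values must all be positive.",
          class = "glycofibril_domain_error")
  }
  as_tibble(reg)
}

#' Look up one sugar
#'
#' @param name Sugar name as in the registry (case-insensitive).
#' @param registry A registry tibble from [sugar_registry()].
#' @return A one-row list with `name`, `molar_mass`, `electrons`, `tpsa`.
#' @examples
#' get_sugar("ribose")$electrons # 80
#' @export
get_sugar <- function(name, registry = sugar_registry()) {
  hit <- registry[tolower(registry$name) == tolower(name), ]
  if (nrow(hit) != 1) {
    abort(paste0("sugar '", name, "' not found in registry."),
          class = "glycofibril_lookup_error")
  }
  as.list(hit)
}
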