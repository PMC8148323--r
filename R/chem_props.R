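# Chemical property sets: diffusivities and partition coefficients that
# parameterize every uptake computation in the package.

#' Construct a chemical species record
#'
#' A `chemical_species` bundles the physicochemical constants that govern
#' vapor-phase transport (gas diffusivity), condensed-phase transport
#' (per-layer diffusivities) and solubility-driven uptake (air/liquid
#' partition coefficients).
#'
#' @param name Species label.
#' @param molar_mass Molar mass in g/mol.
#' @param D_air Gas-phase diffusivity in air, m^2/s.
#' @param D_layer Named list of condensed-phase diffusivities (m^2/s), one
#'   entry per tissue/skin layer name the species will be simulated in
#'   (e.g. `mucus`, `epithelium`, `subepithelium`, `stratum_corneum`).
#' @param K_mucus_air Dimensionless mucus:air equilibrium partition
#'   coefficient (condensed-phase concentration over gas-phase concentration
#'   at the interface).
#' @param K_skin_air Dimensionless skin-surface:air partition coefficient.
#' @param gas_film_coeff Optional gas-side mass-transfer coefficient
#'   override, m/s. When `NULL` the transport modules derive one from a
#'   Sherwood-number correlation on the local hydraulic diameter.
#'
#' @return An object of class `chemical_species`.
#' @export
#' @examples
#' thc <- thc_defaults()
#' thc$K_mucus_air
chemical_species <- function(name, molar_mass, D_air, D_layer,
                             K_mucus_air, K_skin_air,
                             gas_film_coeff = NULL) {
  check_positive(molar_mass, "molar_mass")
  check_positive(D_air, "D_air")
  if (!is.list(D_layer) || is.null(names(D_layer)) || any(names(D_layer) == "")) {
    stop_invalid("`D_layer` must be a named list of diffusivities")
  }
  for (nm in names(D_layer)) check_positive(D_layer[[nm]], paste0("D_layer$", nm))
  if (any(unlist(D_layer) >= D_air)) {
    stop_invalid("gas-phase diffusivity D_air must exceed every D_layer entry")
  }
  check_nonneg(K_mucus_air, "K_mucus_air")
  check_nonneg(K_skin_air, "K_skin_air")
  if (!is.null(gas_film_coeff)) check_positive(gas_film_coeff, "gas_film_coeff")
  structure(
    list(name = as.character(name), molar_mass = molar_mass, D_air = D_air,
         D_layer = D_layer, K_mucus_air = K_mucus_air,
         K_skin_air = K_skin_air, gas_film_coeff = gas_film_coeff),
    class = "chemical_species"
  )
}

#' @export
print.chemical_species <- function(x, ...) {
  cat("<chemical_species>", x$name, "\n")
  cat("  M       :", x$molar_mass, "g/mol\n")
  cat("  D_air   :", format(x$D_air, digits = 3), "m^2/s\n")
  cat("  K (muc) :", format(x$K_mucus_air, digits = 3),
      "  K (skin):", format(x$K_skin_air, digits = 3), "\n")
  invisible(x)
}

# Fuller atomic diffusion volumes, air partner constants.
.FULLER_AIR <- list(M = 28.97, V = 19.7)

#' Estimate a binary gas-phase diffusivity in air
#'
#' Fuller-Schettler-Giddings correlation for the diffusivity of a trace
#' organic vapor in air. Used to populate species defaults when no measured
#' value is supplied.
#'
#' @param molar_mass Solute molar mass, g/mol.
#' @param molar_volume Fuller diffusion volume of the solute, cm^3/mol
#'   (sum of atomic increments).
#' @param temperature Absolute temperature, K. Default 298.15.
#' @param pressure Total pressure, Pa. Default 101325.
#'
#' @return Diffusivity in m^2/s.
#' @export
#' @examples
#' estimate_gas_diffusivity(314.5, 415.4) # THC-like solute, ~4e-6 m^2/s
estimate_gas_diffusivity <- function(molar_mass, molar_volume,
                                     temperature = 298.15,
                                     pressure = 101325) {
  check_positive(molar_mass, "molar_mass")
  check_positive(molar_volume, "molar_volume")
  check_positive(temperature, "temperature")
  check_positive(pressure, "pressure")
  M_ab <- 2 / (1 / molar_mass + 1 / .FULLER_AIR$M)
  p_bar <- pressure / 1e5
  d_cm2s <- 0.00143 * temperature^1.75 /
    (p_bar * sqrt(M_ab) * (molar_volume^(1 / 3) + .FULLER_AIR$V^(1 / 3))^2)
  d_cm2s * 1e-4
}

#' Default THC property set
#'
#' THC (tetrahydrocannabinol, C21H30O2, 314.5 g/mol) configured as a
#' high-solubility vapor: a large mucus:air partition coefficient in the
#' nicotine class, with condensed-phase diffusivities below nicotine's
#' (THC is the larger molecule). All values are declared modeling
#' assumptions, overridable via the scenario config.
#'
#' @return A [chemical_species] record.
#' @export
thc_defaults <- function() {
  chemical_species(
    name = "THC",
    molar_mass = 314.5,
    D_air = estimate_gas_diffusivity(314.5, 415.4),
    D_layer = list(
      mucus          = 4.0e-10,
      epithelium     = 2.0e-10,
      subepithelium  = 2.0e-10,
      surface_lipid  = 1.0e-11,
      stratum_corneum = 1.0e-13,
      viable_epidermis = 1.0e-10
    ),
    K_mucus_air = 5e4,
    K_skin_air  = 5e5
  )
}

#' Default nicotine property set
#'
#' Companion fixture to [thc_defaults()] for firsthand/secondhand
#' comparisons: slightly higher solubility and faster condensed-phase
#' diffusion than THC.
#'
#' @return A [chemical_species] record.
#' @export
nicotine_defaults <- function() {
  chemical_species(
    name = "nicotine",
    molar_mass = 162.2,
    D_air = estimate_gas_diffusivity(162.2, 200.4),
    D_layer = list(
      mucus          = 6.0e-10,
      epithelium     = 3.0e-10,
      subepithelium  = 3.0e-10,
      surface_lipid  = 2.0e-11,
      stratum_corneum = 2.0e-13,
      viable_epidermis = 1.5e-10
    ),
    K_mucus_air = 1e5,
    K_skin_air  = 1e6
  )
}

#' Serialize a species record to JSON
#'
#' Numeric fields survive the round trip bit-exactly
#' (full-precision serialization).
#'
#' @param species A [chemical_species].
#' @param path Optional file path; when `NULL` the JSON string is returned.
#' @return JSON string (invisibly when written to `path`).
#' @export
species_to_json <- function(species, path = NULL) {
  stopifnot(inherits(species, "chemical_species"))
  x <- unclass(species)
  if (is.null(x$gas_film_coeff)) x$gas_film_coeff <- NA_real_
  js <- jsonlite::toJSON(x, auto_unbox = TRUE, digits = I(17), na = "null")
  if (!is.null(path)) {
    writeLines(js, path)
    return(invisible(js))
  }
  js
}

#' @rdname species_to_json
#' @param json JSON string or file path produced by [species_to_json()].
#' @export
species_from_json <- function(json) {
  x <- jsonlite::fromJSON(json, simplifyVector = TRUE)
  chemical_species(
    name = x$name, molar_mass = as.numeric(x$molar_mass),
    D_air = as.numeric(x$D_air),
    D_layer = lapply(as.list(x$D_layer), as.numeric),
    K_mucus_air = as.numeric(x$K_mucus_air),
    K_skin_air = as.numeric(x$K_skin_air),
    gas_film_coeff = if (is.null(x$gas_film_coeff) || is.na(x$gas_film_coeff)) NULL
                     else x$gas_film_coeff
  )
}
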