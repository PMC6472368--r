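#' In-situ environmental conditions
#'
#' Bundle of the environmental state under which reaction energies are
#' evaluated: temperature, hydrostatic pressure, pH and per-species
#' concentrations. The defaults are deep-sea seep sediment conditions:
#' 4 degrees C, 300 atm, pH 8, all solutes at the 1 M standard state except
#' bicarbonate at 2 mM. Water (and any pure liquid) has activity fixed at 1;
#' the proton activity is always `10^-pH` and must not also be given a
#' concentration.
#'
#' @param temperature_C Temperature in degrees Celsius (> -273.15).
#' @param pressure_atm Hydrostatic pressure, atm (> 0). Recorded with the
#'   conditions; by default no pressure term enters the energy correction
#'   (see [insitu_energy()]).
#' @param pH Dimensionless pH; proton activity is `10^-pH`.
#' @param concentrations Named numeric vector of solute/gas concentrations
#'   in mol/L (gas entries are treated as activities); species not listed
#'   default to 1 (standard state). All values must be positive.
#' @return An object of class `seep_conditions`.
#' @examples
#' deep_sea_conditions()
#' conditions(temperature_C = 25, pH = 0)  # standard state
#' @export
conditions <- function(temperature_C = 4, pressure_atm = 300, pH = 8,
                       concentrations = c("HCO3-" = 0.002)) {
  temperature_K <- temperature_C + 273.15
  if (!is.finite(temperature_K) || temperature_K <= 0) {
    abort("temperature must be above absolute zero")
  }
  if (!is.finite(pressure_atm) || pressure_atm <= 0) {
    abort("pressure must be positive")
  }
  if (length(concentrations) > 0) {
    if (is.null(names(concentrations)) || any(!nzchar(names(concentrations)))) {
      abort("concentrations must be a named vector")
    }
    if (any(!is.finite(concentrations) | concentrations <= 0)) {
      abort("concentrations must be positive and finite")
    }
    if ("H+" %in% names(concentrations)) {
      abort("H+ activity is set by pH; do not list it in concentrations")
    }
  }
  structure(
    list(temperature_K = temperature_K, pressure_atm = pressure_atm,
         pH = pH, concentrations = concentrations, water_activity = 1),
    class = "seep_conditions")
}

#' @rdname conditions
#' @export
deep_sea_conditions <- function() conditions()

#' @export
print.seep_conditions <- function(x, ...) {
  cat(sprintf("<seep_conditions> %.2f K (%.1f degC), %g atm, pH %g\n",
              x$temperature_K, x$temperature_K - 273.15, x$pressure_atm, x$pH))
  if (length(x$concentrations)) {
    cat("  non-standard concentrations (mol/L):\n")
    for (nm in names(x$concentrations)) {
      cat(sprintf("    %s = %g\n", nm, x$concentrations[[nm]]))
    }
  } else {
    cat("  all species at 1 M standard state\n")
  }
  invisible(x)
}

# Activity of each species row under the conditions:
# pure liquids -> 1, H+ -> 10^-pH, else concentration (default 1 M).
species_activity <- function(sp, cond) {
  stopifnot(inherits(cond, "seep_conditions"))
  a <- rep(1, nrow(sp))
  listed <- match(sp$name, names(cond$concentrations))
  has <- !is.na(listed)
  a[has] <- cond$concentrations[listed[has]]
  a[sp$phase == "liquid"] <- cond$water_activity
  a[sp$name == "H+"] <- 10^(-cond$pH)
  if (any(!is.finite(a) | a <= 0)) {
    abort(sprintf("non-positive activity for species: %s",
                  paste(sp$name[!is.finite(a) | a <= 0], collapse = ", ")))
  }
  a
}
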