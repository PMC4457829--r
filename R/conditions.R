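#' Experimental conditions for a kinetic experiment
#'
#' @param co_atm equilibration CO pressure in atm.
#' @param temperature_C temperature in degrees Celsius (bookkeeping only;
#'   the scheme is single-temperature).
#' @param co_solubility dissolved CO per atm of CO, M/atm. Default 1.0 mM
#'   per atm at 20 degrees C.
#' @param photolysis_yield fraction of the bound population photolysed by
#'   the laser flash, in \[0, 1\].
#' @param scavenger_mode if `TRUE`, rebinding from the solvent is disabled
#'   (the free ligand is scavenged, as when CO-bound protein is mixed with
#'   excess NO in the stopped flow).
#' @return An object of class `experiment_conditions`.
#' @examples
#' experiment_conditions(co_atm = 0.1)
#' @export
experiment_conditions <- function(co_atm = 1.0, temperature_C = 20,
                                  co_solubility = 1e-3,
                                  photolysis_yield = 1.0,
                                  scavenger_mode = FALSE) {
  if (!is.numeric(co_atm) || length(co_atm) != 1L || !is.finite(co_atm) ||
      co_atm < 0) {
    stop("co_atm must be a single finite non-negative number", call. = FALSE)
  }
  if (!is.numeric(co_solubility) || co_solubility < 0) {
    stop("co_solubility must be non-negative", call. = FALSE)
  }
  if (!is.numeric(photolysis_yield) || length(photolysis_yield) != 1L ||
      photolysis_yield < 0 || photolysis_yield > 1) {
    stop("photolysis_yield must be in [0, 1]", call. = FALSE)
  }
  structure(list(co_atm = co_atm, temperature_C = temperature_C,
                 co_solubility = co_solubility,
                 photolysis_yield = photolysis_yield,
                 scavenger_mode = isTRUE(scavenger_mode)),
            class = "experiment_conditions")
}

#' Dissolved CO concentration implied by a set of conditions
#' @param conditions an [experiment_conditions] object.
#' @return Molar CO concentration.
#' @export
co_molar <- function(conditions) {
  stopifnot(inherits(conditions, "experiment_conditions"))
  conditions$co_atm * conditions$co_solubility
}

#' @export
print.experiment_conditions <- function(x, ...) {
  cat(sprintf(
    "Conditions: %.3g atm CO (%.3g M dissolved), %.3g C, yield %.3g%s\n",
    x$co_atm, co_molar(x), x$temperature_C, x$photolysis_yield,
    if (x$scavenger_mode) ", scavenger mode (no solvent rebinding)" else ""))
  invisible(x)
}
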