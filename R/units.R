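#' Unit conventions
#'
#' All internal computation uses CGS units: lengths in cm, pressures in
#' dyn/cm2, flows in mL/s, resistances in dyn s/cm5, compliances in cm5/dyn.
#' Clinical quantities (mmHg, mL/min, mL/min per 100 mL tissue) are converted
#' exactly once at interfaces.
#'
#' @name units
NULL

# 1 mmHg in dyn/cm2 (see methods vignette for the choice of constant)
MMHG_DYNCM2 <- 1333.22
# 1 Pa in dyn/cm2
PA_DYNCM2 <- 10

#' Convert a pressure between units
#'
#' Exact linear conversion between mmHg, dyn/cm2 and Pa, using
#' 1 mmHg = 1333.22 dyn/cm2 and 1 Pa = 10 dyn/cm2.
#'
#' @param value numeric vector of pressures.
#' @param from,to one of `"mmHg"`, `"dyn/cm2"`, `"Pa"`.
#' @return numeric vector in the target unit.
#' @examples
#' convert_pressure(15, "mmHg", "dyn/cm2")
#' @export
convert_pressure <- function(value, from, to) {
  factors <- c("mmHg" = MMHG_DYNCM2, "dyn/cm2" = 1, "Pa" = PA_DYNCM2)
  if (!from %in% names(factors)) {
    stop("unknown pressure unit: ", from)
  }
  if (!to %in% names(factors)) {
    stop("unknown pressure unit: ", to)
  }
  value * factors[[from]] / factors[[to]]
}

mmHg_to_cgs <- function(p) p * MMHG_DYNCM2
cgs_to_mmHg <- function(p) p / MMHG_DYNCM2

#' Blood fluid properties
#'
#' Dynamic viscosity in Poise (dyn s/cm2) and density in g/cm3. Defaults are
#' the Newtonian-blood values used throughout coronary hemodynamics modeling;
#' the Newtonian assumption is reasonable above roughly 300 um vessel
#' diameter, the smallest caliber represented here.
#'
#' @param viscosity dynamic viscosity \[Poise\].
#' @param density density \[g/cm3\].
#' @return an object of class `fluid_properties`.
#' @export
fluid_properties <- function(viscosity = 0.04, density = 1.06) {
  if (!is.numeric(viscosity) || length(viscosity) != 1L || viscosity <= 0) {
    stop("viscosity must be a positive scalar")
  }
  if (!is.numeric(density) || length(density) != 1L || density <= 0) {
    stop("density must be a positive scalar")
  }
  structure(list(viscosity = viscosity, density = density),
            class = "fluid_properties")
}
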