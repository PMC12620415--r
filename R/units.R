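#' Unit conversion constants
#'
#' All internal computation runs in CGS units (dyn, cm, s). Clinical units
#' (mmHg, L/min, Wood units, Pa.s) are converted at the package boundary with
#' these factors.
#'
#' @format Named numeric constants:
#' \describe{
#'   \item{MMHG_TO_DYN_CM2}{1 mmHg = 1333.22 dyn/cm^2}
#'   \item{LMIN_TO_CM3_S}{1 L/min = 16.6667 cm^3/s}
#'   \item{WU_TO_DYN_S_CM5}{1 Wood unit = 80 dyn.s/cm^5}
#'   \item{PAS_TO_POISE}{1 Pa.s = 10 poise}
#' }
#' @name units
#' @keywords internal
NULL

MMHG_TO_DYN_CM2 <- 1333.22
LMIN_TO_CM3_S <- 16.6667
WU_TO_DYN_S_CM5 <- 80
PAS_TO_POISE <- 10

mmhg_to_cgs <- function(x) x * MMHG_TO_DYN_CM2
cgs_to_mmhg <- function(x) x / MMHG_TO_DYN_CM2
lmin_to_cgs <- function(x) x * LMIN_TO_CM3_S
wu_to_cgs <- function(x) x * WU_TO_DYN_S_CM5
cgs_to_wu <- function(x) x / WU_TO_DYN_S_CM5

#' Blood rheology model
#'
#' Newtonian blood model with the constant viscosity and density used for the
#' pulmonary circulation simulations.
#'
#' @param viscosity Dynamic viscosity in Pa.s. Default 0.0035.
#' @param density Density in kg/m^3. Default 1060 (carried for completeness;
#'   the resistive 0D network is inertia-free and does not use it).
#'
#' @return A list of class `blood_model` with elements `viscosity` (Pa.s),
#'   `density` (kg/m^3) and `viscosity_poise` (CGS).
#' @export
#' @examples
#' blood_model()
blood_model <- function(viscosity = 0.0035, density = 1060) {
  if (!is.numeric(viscosity) || length(viscosity) != 1 || viscosity <= 0) {
    stop("`viscosity` must be a single positive number (Pa.s)", call. = FALSE)
  }
  if (!is.numeric(density) || length(density) != 1 || density <= 0) {
    stop("`density` must be a single positive number (kg/m^3)", call. = FALSE)
  }
  structure(
    list(
      viscosity = viscosity,
      density = density,
      viscosity_poise = viscosity * PAS_TO_POISE
    ),
    class = "blood_model"
  )
}
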