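#' Thermodynamic constants
#'
#' Bundle of the gas constant, temperature and their product RT, used by every
#' thermodynamic computation in the package. The defaults (R = 8.314e-3
#' kJ mol^-1 K^-1, T = 298.15 K) are the standard-condition convention; they
#' give RT ~ 2.479 kJ/mol so that a driving force of 7.3 kJ/mol corresponds to
#' a forward/reverse flux ratio of exp(7.3/RT) = 19.
#'
#' @param gas_constant_R Gas constant in kJ mol^-1 K^-1.
#' @param temperature_T Absolute temperature in K.
#' @return An object of class `thermo_constants`: a list with elements
#'   `R`, `T` and `RT` (kJ/mol).
#' @examples
#' k <- thermo_constants()
#' k$RT # ~ 2.479 kJ/mol
#' @export
thermo_constants <- function(gas_constant_R = 8.314e-3, temperature_T = 298.15) {
  stopifnot(is.numeric(gas_constant_R), length(gas_constant_R) == 1L,
            is.finite(gas_constant_R), gas_constant_R > 0,
            is.numeric(temperature_T), length(temperature_T) == 1L,
            is.finite(temperature_T), temperature_T > 0)
  structure(list(R = gas_constant_R, T = temperature_T,
                 RT = gas_constant_R * temperature_T),
            class = "thermo_constants")
}

# shared input check for the flux-force functions
check_dg <- function(dg_prime) {
  if (!is.numeric(dg_prime) || length(dg_prime) == 0L || any(!is.finite(dg_prime))) {
    stop("`dg_prime` must be finite numeric (kJ/mol); got ",
         deparse(substitute(dg_prime)), call. = FALSE)
  }
  invisible(dg_prime)
}

#' Forward-to-reverse flux ratio of a reaction
#'
#' The flux-force relationship states dG' = -RT * ln(J+/J-), so the ratio of
#' forward to reverse one-way fluxes is exp(-dG'/RT). A reaction with
#' dG' = -5.7 kJ/mol runs forward roughly ten times faster than backward.
#'
#' @param dg_prime Transformed reaction Gibbs energy dG' in kJ/mol
#'   (vectorized).
#' @param constants A [thermo_constants()] object.
#' @return Positive numeric vector, `exp(-dg_prime / RT)`. The exponent is
#'   capped at +-700 to avoid floating overflow; this changes nothing at any
#'   printed precision.
#' @export
forward_reverse_ratio <- function(dg_prime, constants = thermo_constants()) {
  check_dg(dg_prime)
  z <- -dg_prime / constants$RT
  exp(pmin(pmax(z, -700), 700))
}

#' Fraction of total flux running in reverse
#'
#' The reverse one-way flux as a fraction of the total (forward + reverse)
#' flux: J-/(J+ + J-) = 1/(1 + exp(-dG'/RT)). At dG' = -7.3 kJ/mol about 5%
#' of the catalytic events are reverse; at -1 kJ/mol about 40%.
#'
#' @inheritParams forward_reverse_ratio
#' @return Numeric vector in (0, 1). Computed via the logistic function,
#'   which is overflow-safe for any finite argument.
#' @export
reverse_flux_fraction <- function(dg_prime, constants = thermo_constants()) {
  check_dg(dg_prime)
  stats::plogis(dg_prime / constants$RT)
}

#' Flux-force efficacy
#'
#' The net flux as a fraction of the total flux,
#' (J+ - J-)/(J+ + J-) = tanh(-dG'/(2 RT)): the fraction of the enzyme's
#' catalytic capacity realized as net flux. Near equilibrium the efficacy
#' drops toward zero (enzyme wasted on reverse catalysis); it is negative
#' when dG' > 0, i.e. when the net flux runs against the nominal direction.
#'
#' @inheritParams forward_reverse_ratio
#' @return Numeric vector in (-1, 1).
#' @examples
#' flux_force_efficacy(-7.3) # ~ 0.90
#' flux_force_efficacy(-1)   # ~ 0.20
#' @export
flux_force_efficacy <- function(dg_prime, constants = thermo_constants()) {
  check_dg(dg_prime)
  tanh(-dg_prime / (2 * constants$RT))
}
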