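## Two-point temperature machinery linking the 70 degC and 80 degC model
## parameterizations.  Enzyme-catalyzed rate constants follow the
## Arrhenius law k = A exp(-Ei/(R T)); with a characteristic activation
## enthalpy of 60 kJ/mol a +10 degC step around 70-80 degC multiplies k
## by about 1.8, i.e. velocities approximately double, which is the
## empirical Van't Hoff rule used to map parameter sets between the two
## temperatures.

#' Arrhenius rate ratio across a temperature step
#'
#' Ratio `k(T2)/k(T1) = exp(Ei/R * (1/T1 - 1/T2))` of a rate constant at
#' the upper over the lower temperature.  For the default activation
#' enthalpy of 60 kJ/mol between 343.15 K (70 degC) and 353.15 K
#' (80 degC) the ratio is 1.814, in line with the Van't Hoff doubling
#' rule.
#'
#' @param Ei Activation enthalpy in J/mol (default 60000).
#' @param T1 Lower temperature in K (default 343.15).
#' @param T2 Upper temperature in K (default 353.15).
#' @param R Gas constant, J/(mol K).
#' @return Dimensionless ratio `k(T2)/k(T1)`.
#' @export
arrhenius_rate_ratio <- function(Ei = 60000, T1 = 343.15, T2 = 353.15,
                                 R = 8.314) {
  if (T1 <= 0 || T2 <= 0) stop("temperatures must be positive (Kelvin)")
  if (Ei < 0) stop("activation enthalpy must be non-negative")
  exp(Ei / R * (1 / T1 - 1 / T2))
}

#' Map a parameter set across a 10 degC step by the Van't Hoff rule
#'
#' `up10` doubles every maximal velocity (measured, free, and the
#' first-order sink constants); `down10` halves them.  Km and Ki are
#' temperature-independent and untouched.  Degradation rates are NOT
#' rescaled: half-lives of the thermolabile intermediates are measured
#' per temperature and must be supplied for the target temperature by the
#' caller (via `half_life`).
#'
#' @param params An `ed_parameters` object.
#' @param direction `"up10"` (double) or `"down10"` (halve).
#' @param half_life Optional named replacement half-lives (min) for the
#'   target temperature.
#' @return A new `ed_parameters` at `temperature +/- 10`.
#' @export
vant_hoff_transform <- function(params, direction = c("up10", "down10"),
                                half_life = NULL) {
  direction <- match.arg(direction)
  f <- if (direction == "up10") 2 else 0.5
  params$vmax <- params$vmax * f
  params$vmax_sd <- params$vmax_sd * f
  params$sink_rates <- params$sink_rates * f
  params$temperature <- params$temperature + if (f == 2) 10 else -10
  if (!is.null(half_life)) params$half_life[names(half_life)] <- half_life
  params
}

#' Check Van't Hoff consistency of two measured velocity sets
#'
#' Computes the per-reaction ratios `v80/v70` and their arithmetic mean;
#' the rule predicts a mean of about 2 for a 10 degC step.  Reactions
#' deviating from 2 by more than `flag_fraction` (relative) are flagged.
#'
#' @param v70,v80 Named velocity vectors sharing the same names.
#' @param flag_fraction Relative deviation from 2 that triggers a flag
#'   (default 0.5, i.e. outside `[1, 3]`).
#' @return List with `mean_ratio`, `ratios` and logical `flagged`.
#' @export
check_vant_hoff <- function(v70, v80, flag_fraction = 0.5) {
  if (!setequal(names(v70), names(v80))) stop("velocity name sets differ")
  v80 <- v80[names(v70)]
  if (any(v70 == 0)) stop("zero-valued 70 degC velocity: ",
                          paste(names(v70)[v70 == 0], collapse = ", "))
  ratios <- v80 / v70
  list(mean_ratio = mean(ratios), ratios = ratios,
       flagged = abs(ratios - 2) / 2 > flag_fraction)
}
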