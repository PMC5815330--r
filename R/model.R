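#' Two-state melting model parameters
#'
#' Constructs the parameter set of the intramolecular two-state van't Hoff
#' melting model with sloping linear baselines: folding enthalpy `dH`
#' (kcal mol^-1, negative for a hairpin that is stable at low temperature),
#' melting temperature `tm` (Kelvin, where folded and unfolded populations are
#' equal), and a linear absorbance baseline for each of the pure folded and
#' pure unfolded states. Baselines are parameterized as
#' `intercept + slope * (T - ref_temp)` so that intercepts are the absorbance
#' at `ref_temp` (normally the lowest observed temperature), which keeps slope
#' and intercept estimates decorrelated in fits.
#'
#' A physically sensible hairpin melt is hyperchromic: the unfolded baseline
#' lies at or above the folded baseline at `tm`. Violations are flagged with a
#' warning, not an error, since noisy fits can cross.
#'
#' @param dH folding enthalpy, kcal mol^-1; finite and nonzero.
#' @param tm melting temperature, Kelvin; positive.
#' @param folded_slope,folded_intercept folded-state baseline, AU K^-1 and AU.
#' @param unfolded_slope,unfolded_intercept unfolded-state baseline.
#' @param ref_temp Kelvin; temperature at which the intercepts are defined.
#' @return An object of class `two_state_params` (a named list).
#' @examples
#' two_state_params(dH = -42.2, tm = 341.1)
#' @export
two_state_params <- function(dH, tm,
                             folded_slope = 0, folded_intercept = 0.65,
                             unfolded_slope = 0, unfolded_intercept = 0.75,
                             ref_temp = celsius_to_kelvin(10)) {
  if (!is.finite(dH) || dH == 0) {
    abort("`dH` must be finite and nonzero.", class = "tetramelt_domain_error")
  }
  if (!is.finite(tm) || tm <= 0) {
    abort("`tm` must be a positive temperature in Kelvin.",
          class = "tetramelt_domain_error")
  }
  p <- structure(
    list(dH = dH, tm = tm,
         folded_slope = folded_slope, folded_intercept = folded_intercept,
         unfolded_slope = unfolded_slope, unfolded_intercept = unfolded_intercept,
         ref_temp = ref_temp),
    class = "two_state_params"
  )
  bf_tm <- folded_intercept + folded_slope * (tm - ref_temp)
  bu_tm <- unfolded_intercept + unfolded_slope * (tm - ref_temp)
  if (bu_tm < bf_tm) {
    warn("Unfolded baseline lies below folded baseline at tm: not hyperchromic.",
         class = "tetramelt_hyperchromicity_warning")
  }
  p
}

#' @export
print.two_state_params <- function(x, ...) {
  cat("Two-state melt parameters\n")
  cat(sprintf("  dH  %8.2f kcal/mol   tm %7.2f K (%.2f degC)\n",
              x$dH, x$tm, kelvin_to_celsius(x$tm)))
  cat(sprintf("  folded baseline:   %.5f + %.2e * (T - %.2f)\n",
              x$folded_intercept, x$folded_slope, x$ref_temp))
  cat(sprintf("  unfolded baseline: %.5f + %.2e * (T - %.2f)\n",
              x$unfolded_intercept, x$unfolded_slope, x$ref_temp))
  invisible(x)
}

#' Fraction of molecules folded at a temperature
#'
#' Evaluates the two-state van't Hoff population of the folded state for a
#' unimolecular (hairpin) transition with no heat-capacity change:
#' `K(T) = exp(-(dH/R) * (1/T - 1/tm))` for the unfolded-to-folded
#' equilibrium, and `f = K / (1 + K)`. At `T = tm`, `K = 1` and `f = 0.5`
#' exactly; for a stable hairpin (`dH < 0`) `f` decreases monotonically with
#' temperature.
#'
#' @param temp_K temperature(s), Kelvin; must be positive.
#' @param dH folding enthalpy, kcal mol^-1.
#' @param tm melting temperature, Kelvin.
#' @return numeric vector of folded fractions in (0, 1).
#' @examples
#' fraction_folded(341.1, dH = -42.2, tm = 341.1) # 0.5
#' @export
fraction_folded <- function(temp_K, dH, tm) {
  if (any(!is.finite(temp_K)) || any(temp_K <= 0)) {
    abort("`temp_K` must be positive and finite (Kelvin).",
          class = "tetramelt_domain_error")
  }
  if (!is.finite(dH)) abort("`dH` must be finite.", class = "tetramelt_domain_error")
  if (!is.finite(tm) || tm <= 0) {
    abort("`tm` must be positive (Kelvin).", class = "tetramelt_domain_error")
  }
  lnK <- -(dH / thermo_constants()$R_gas) * (1 / temp_K - 1 / tm)
  # logistic form is overflow-safe for the exp(lnK)/(1+exp(lnK)) ratio
  plogis(lnK)
}

#' Model absorbance of a melting hairpin
#'
#' The observable: a population-weighted mix of the two linear state baselines,
#' `A(T) = f(T) * B_folded(T) + (1 - f(T)) * B_unfolded(T)`. Tends to the
#' folded baseline at low temperature and to the unfolded baseline at high
#' temperature (for `dH < 0`), with the sigmoidal transition centred at `tm`.
#'
#' @param temp_K temperature(s), Kelvin.
#' @param params a [two_state_params()] object.
#' @return numeric vector of absorbances (AU).
#' @export
model_absorbance <- function(temp_K, params) {
  stopifnot(inherits(params, "two_state_params"))
  f <- fraction_folded(temp_K, params$dH, params$tm)
  dT <- temp_K - params$ref_temp
  bf <- params$folded_intercept + params$folded_slope * dT
  bu <- params$unfolded_intercept + params$unfolded_slope * dT
  f * bf + (1 - f) * bu
}

#' Derive thermodynamic parameters from a fitted transition
#'
#' For a unimolecular two-state transition the equilibrium constant is 1 at
#' the melting temperature, so `dS = 1000 * dH / tm` (entropy in cal mol^-1
#' K^-1, "entropy units") and the standard folding free energy at 37 degC is
#' `dG37 = dH - 310.15 * dS / 1000` (kcal mol^-1). These identities hold
#' exactly per fit; condition-level summaries average each parameter
#' independently across replicates and are not forced to satisfy them.
#'
#' @param dH folding enthalpy (kcal mol^-1); vectorized.
#' @param tm melting temperature, Kelvin; vectorized.
#' @return A tibble with columns `dH` (kcal mol^-1), `dS` (e.u.),
#'   `tm_celsius` (degC), `dG37` (kcal mol^-1).
#' @examples
#' derive_thermo(dH = -42.2, tm = 42200 / 123.7)
#' @export
derive_thermo <- function(dH, tm) {
  if (any(!is.finite(tm)) || any(tm <= 0)) {
    abort("`tm` must be positive (Kelvin).", class = "tetramelt_domain_error")
  }
  cst <- thermo_constants()
  dS <- 1000 * dH / tm
  tibble::tibble(
    dH = dH,
    dS = dS,
    tm_celsius = kelvin_to_celsius(tm),
    dG37 = dH - cst$T37 * dS / 1000
  )
}
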