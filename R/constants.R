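# Physical constants used throughout. Single source of truth: every module
# pulls these through thermo_constants(), never redefines them.
.tetramelt_constants <- list(
  R_gas          = 0.001987, # gas constant, kcal mol^-1 K^-1
  T37            = 310.15,   # 37 degC in Kelvin; reference T for dG37
  celsius_offset = 273.15,
  # Free-energy contribution of the change in stem stacking when a GC closing
  # pair replaces a CG; subtracted from the GC-vs-CG difference to isolate the
  # loop term. Treated as exact (no uncertainty).
  loop_stacking_correction = 0.16 # kcal mol^-1
)

#' Thermodynamic constants
#'
#' Returns the immutable physical constants used by every computation in the
#' package: the gas constant in kcal units, 37 degC in Kelvin, the
#' Celsius-to-Kelvin offset, and the stacking correction applied when isolating
#' the loop contribution from a GC-vs-CG closing-base-pair free-energy
#' difference.
#'
#' @return A named list with elements `R_gas` (kcal mol^-1 K^-1), `T37` (K),
#'   `celsius_offset`, and `loop_stacking_correction` (kcal mol^-1).
#' @examples
#' thermo_constants()$R_gas
#' @export
thermo_constants <- function() .tetramelt_constants

#' Convert between Celsius and Kelvin
#'
#' All internal thermodynamics are computed in Kelvin; user-facing tables and
#' melt files carry degrees Celsius.
#'
#' @param temp_C,temp_K numeric temperature vectors.
#' @return numeric vector in the other unit.
#' @examples
#' celsius_to_kelvin(37) # 310.15
#' @export
celsius_to_kelvin <- function(temp_C) temp_C + .tetramelt_constants$celsius_offset

#' @rdname celsius_to_kelvin
#' @export
kelvin_to_celsius <- function(temp_K) temp_K - .tetramelt_constants$celsius_offset
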