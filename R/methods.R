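#' Tidy a two-state melt fit
#'
#' @param x a `melt_fit` from [fit_two_state()].
#' @param ... unused.
#' @return tibble with one row per fitted parameter: `term`, `estimate`,
#'   `std.error`. `dH` is kcal mol^-1, `tm` Kelvin, slopes AU K^-1 and
#'   intercepts AU (at the fit's reference temperature).
#' @method tidy melt_fit
#' @export
tidy.melt_fit <- function(x, ...) {
  p <- x$params
  est <- c(dH = p$dH, tm = p$tm,
           folded_slope = p$folded_slope, folded_intercept = p$folded_intercept,
           unfolded_slope = p$unfolded_slope, unfolded_intercept = p$unfolded_intercept)
  se <- setNames(x$param_sd[c("dH", "tm", "fs", "fi", "us", "ui")], names(est))
  tibble::tibble(term = names(est), estimate = unname(est), std.error = unname(se))
}

#' One-row summary of a two-state melt fit
#'
#' @param x a `melt_fit`.
#' @param ... unused.
#' @return one-row tibble: derived thermodynamics (`dH`, `dS`, `tm_celsius`,
#'   `dG37`), `dH_se`, `tm_se`, `residual_sd`, `converged`, `n_iter`, `nobs`,
#'   `n_warnings`.
#' @method glance melt_fit
#' @export
glance.melt_fit <- function(x, ...) {
  th <- derive_thermo(x$params$dH, x$params$tm)
  dplyr::bind_cols(th, tibble::tibble(
    dH_se = unname(x$param_sd["dH"]), tm_se = unname(x$param_sd["tm"]),
    residual_sd = x$residual_sd, converged = x$converged,
    n_iter = x$n_iter, nobs = nrow(x$data), n_warnings = length(x$warnings)
  ))
}

#' Augment melt-curve data with fitted values
#'
#' @param x a `melt_fit`.
#' @param ... unused.
#' @return the fitted curve data plus `.fitted`, `.resid` and
#'   `.fraction_folded` columns.
#' @method augment melt_fit
#' @export
augment.melt_fit <- function(x, ...) {
  tK <- celsius_to_kelvin(x$data$temperature_C)
  fitted <- model_absorbance(tK, x$params)
  dplyr::mutate(tibble::as_tibble(x$data),
                .fitted = fitted,
                .resid = .data$absorbance - fitted,
                .fraction_folded = fraction_folded(tK, x$params$dH, x$params$tm))
}

#' Plot a melt fit: data, model curve, and state baselines
#'
#' @param object a `melt_fit`.
#' @param ... unused.
#' @return a ggplot: observed absorbance (points), fitted two-state curve
#'   (line), and the extrapolated folded/unfolded baselines (dashed).
#' @method autoplot melt_fit
#' @export
autoplot.melt_fit <- function(object, ...) {
  aug <- augment(object)
  p <- object$params
  dT <- celsius_to_kelvin(aug$temperature_C) - p$ref_temp
  base <- tibble::tibble(
    temperature_C = rep(aug$temperature_C, 2),
    absorbance = c(p$folded_intercept + p$folded_slope * dT,
                   p$unfolded_intercept + p$unfolded_slope * dT),
    state = rep(c("folded", "unfolded"), each = nrow(aug))
  )
  ggplot2::ggplot(aug, ggplot2::aes(x = .data$temperature_C)) +
    ggplot2::geom_point(ggplot2::aes(y = .data$absorbance),
                        size = 0.8, alpha = 0.6) +
    ggplot2::geom_line(ggplot2::aes(y = .data$.fitted), colour = "grey40") +
    ggplot2::geom_line(data = base,
                       ggplot2::aes(y = .data$absorbance, group = .data$state),
                       linetype = "dashed", colour = "steelblue") +
    ggplot2::labs(x = "Temperature (°C)", y = "Absorbance (AU)") +
    ggplot2::theme_minimal()
}

#' Plot normalized melt curves by condition
#'
#' Overlays baseline-normalized (fraction-unfolded) curves, the standard way
#' melting transitions are compared across sequences and cosolute
#' backgrounds: a shift of the sigmoid to lower temperature reads directly as
#' destabilization.
#'
#' @param normalized tibble from [normalized_curve()] calls bound together,
#'   with a grouping column.
#' @param colour name of the column mapped to colour (default `"sample_id"`).
#' @return a ggplot.
#' @export
plot_normalized_curves <- function(normalized, colour = "sample_id") {
  ggplot2::ggplot(normalized,
                  ggplot2::aes(x = .data$temperature_C,
                               y = .data$fraction_unfolded,
                               colour = .data[[colour]])) +
    ggplot2::geom_point(size = 0.5, alpha = 0.5) +
    ggplot2::labs(x = "Temperature (°C)", y = "Fraction unfolded") +
    ggplot2::theme_minimal()
}
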