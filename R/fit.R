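# Two-state model evaluated on plain vectors; the nls formula interface and
# the grid-search oracle both call this.
.melt_model <- function(temp_K, dH, tm, fs, fi, us, ui, ref_temp) {
  lnK <- -(dH / .tetramelt_constants$R_gas) * (1 / temp_K - 1 / tm)
  f <- plogis(lnK)
  dT <- temp_K - ref_temp
  f * (fi + fs * dT) + (1 - f) * (ui + us * dT)
}

.validate_curve <- function(curve) {
  if (!all(c("temperature_C", "absorbance") %in% names(curve))) {
    abort("Curve needs `temperature_C` and `absorbance` columns.",
          class = "tetramelt_curve_error")
  }
  if (nrow(curve) < 8) {
    abort("Curve has fewer than 8 points; the 6-parameter fit is underdetermined.",
          class = "tetramelt_curve_error")
  }
  if (anyNA(curve$temperature_C) || anyNA(curve$absorbance) ||
      any(!is.finite(curve$temperature_C)) || any(!is.finite(curve$absorbance))) {
    abort("Curve contains missing or non-finite values.",
          class = "tetramelt_curve_error")
  }
  if (any(diff(curve$temperature_C) <= 0)) {
    abort("Temperatures must be strictly increasing.",
          class = "tetramelt_curve_error")
  }
  invisible(curve)
}

# centered moving average, window forced odd; ends padded by shrinking window
.smooth_ma <- function(x, w) {
  w <- max(3L, as.integer(w))
  if (w %% 2L == 0L) w <- w + 1L
  h <- (w - 1L) %/% 2L
  n <- length(x)
  vapply(seq_len(n), function(i) {
    lo <- max(1L, i - h); hi <- min(n, i + h)
    mean(x[lo:hi])
  }, numeric(1))
}

#' Data-driven starting parameters for a two-state melt fit
#'
#' Builds an initial [two_state_params()] estimate from the curve alone:
#' state baselines from straight-line fits to the first and last 15% of
#' points, the melting temperature from the extremum of the smoothed
#' derivative dA/dT (centred moving average, window the larger of 5 points
#' and 5% of the curve), and the enthalpy from the two-state derivative
#' relation at the midpoint, `d(fraction unfolded)/dT at tm = -dH/(4 R tm^2)`,
#' applied to the baseline-normalized derivative. When two derivative extrema
#' tie, the one nearer the median temperature is taken (deterministic).
#'
#' A curve with no discernible transition — derivative extremum within 3x the
#' point-to-point derivative noise — raises a "no transition detected" error.
#' A transition oriented the wrong way (absorbance decreasing on melting)
#' yields a positive enthalpy guess and a warning rather than an error.
#'
#' @param curve tibble with `temperature_C` and `absorbance` columns.
#' @return a [two_state_params()] starting estimate with `ref_temp` set to the
#'   lowest observed temperature.
#' @export
initial_guess <- function(curve) {
  .validate_curve(curve)
  tC <- curve$temperature_C
  tK <- celsius_to_kelvin(tC)
  a <- curve$absorbance
  n <- length(a)
  ref <- min(tK)

  n_edge <- max(3L, ceiling(0.15 * n))
  fit_lo <- lm(a[seq_len(n_edge)] ~ I(tK[seq_len(n_edge)] - ref))
  idx_hi <- seq.int(n - n_edge + 1L, n)
  fit_hi <- lm(a[idx_hi] ~ I(tK[idx_hi] - ref))
  bf <- unname(coef(fit_lo)) # folded: low-T end
  bu <- unname(coef(fit_hi)) # unfolded: high-T end

  w <- max(5L, ceiling(0.05 * n))
  if (w %% 2L == 0L) w <- w + 1L
  a_s <- .smooth_ma(a, w)
  d <- diff(a_s) / diff(tK) # derivative at midpoints
  t_mid <- (tK[-1] + tK[-n]) / 2
  # ends of the smoothed curve use truncated windows; keep only derivative
  # points whose window fits entirely inside the data
  h <- (w - 1L) %/% 2L
  interior <- seq.int(h + 1L, length(d) - h)
  d_in <- d[interior]
  t_in <- t_mid[interior]

  # transition signal = derivative in excess of the interpolated baseline
  # slopes; robust for broad transitions, where the raw derivative is elevated
  # over much of the grid
  bg <- bf[2] + (bu[2] - bf[2]) * (t_in - min(t_in)) / (max(t_in) - min(t_in))
  sig <- d_in - bg
  dev <- abs(sig)
  noise <- mad(diff(d_in)) / sqrt(2)
  if (max(dev) <= 3 * noise + 1e-12) {
    abort("No transition detected: derivative extremum indistinct from noise.",
          class = "tetramelt_no_transition_error")
  }
  peak_idx <- which(dev == max(dev))
  if (length(peak_idx) > 1L) { # tie: nearest the median temperature
    peak_idx <- peak_idx[which.min(abs(t_in[peak_idx] - median(tK)))]
  }
  tm_guess <- t_in[peak_idx]

  # Enthalpy from the midpoint slope relation, normalizing the excess
  # derivative by the absolute baseline separation so the curve's own
  # orientation decides the sign: a rising (hyperchromic) sigmoid gives
  # dH < 0, a falling one dH > 0.
  denom <- abs((bu[1] + bu[2] * (tm_guess - ref)) - (bf[1] + bf[2] * (tm_guess - ref)))
  if (denom < .Machine$double.eps * 100) denom <- 1e-6
  du_dT <- sig[peak_idx] / denom
  dH_guess <- -4 * thermo_constants()$R_gas * tm_guess^2 * du_dT
  if (dH_guess > 0) {
    warn("Positive enthalpy guess: curve appears unfolding-oriented (absorbance falls on melting).",
         class = "tetramelt_orientation_warning")
  }
  if (dH_guess == 0) dH_guess <- -1e-3

  two_state_params(
    dH = dH_guess, tm = tm_guess,
    folded_slope = bf[2], folded_intercept = bf[1],
    unfolded_slope = bu[2], unfolded_intercept = bu[1],
    ref_temp = ref
  )
}

#' Fit the two-state melting model to one curve
#'
#' Nonlinear least squares (Levenberg-Marquardt, via \pkg{minpack.lm}) of the
#' six-parameter two-state model — enthalpy, melting temperature, and a
#' sloping linear baseline for each state — to an absorbance melt curve.
#' Baselines are fit jointly with the transition, never pre-subtracted, and
#' the fit is unweighted (homoscedastic noise assumed). The melting
#' temperature is constrained inside the observed temperature range; a
#' warning is recorded when it lands within 5 degC of either end, where the
#' adjacent baseline is poorly determined.
#'
#' Non-convergence is reported in the returned object (`converged = FALSE`
#' with diagnostics), not thrown; a singular covariance leaves the
#' standard errors `NA` with a warning recorded.
#'
#' @param curve tibble with `temperature_C`, `absorbance` (and optionally
#'   metadata columns, carried through to `augment()`).
#' @param init optional [two_state_params()] start; defaults to
#'   [initial_guess()].
#' @param max_iter maximum Levenberg-Marquardt iterations.
#' @return A `melt_fit` object; see [tidy.melt_fit()], [glance.melt_fit()],
#'   [augment.melt_fit()], [autoplot.melt_fit()].
#' @examples
#' curve <- simulate_melt_curve(two_state_params(-42.2, 341.1,
#'   folded_slope = 2e-4, unfolded_slope = 1e-4,
#'   folded_intercept = 0.65, unfolded_intercept = 0.7475,
#'   ref_temp = celsius_to_kelvin(10)), noise_sd = 0, seed = 1)
#' fit <- fit_two_state(curve)
#' glance(fit)
#' @export
fit_two_state <- function(curve, init = NULL, max_iter = 200) {
  .validate_curve(curve)
  warnings <- character()
  init <- init %||% withCallingHandlers(
    initial_guess(curve),
    warning = function(w) {
      warnings <<- c(warnings, conditionMessage(w))
      invokeRestart("muffleWarning")
    }
  )
  tK <- celsius_to_kelvin(curve$temperature_C)
  ref <- min(tK)
  dat <- data.frame(tK = tK, absorbance = curve$absorbance)

  start <- list(dH = init$dH, tm = init$tm,
                fs = init$folded_slope, fi = init$folded_intercept,
                us = init$unfolded_slope, ui = init$unfolded_intercept)
  lower <- c(dH = -Inf, tm = min(tK), fs = -Inf, fi = -Inf, us = -Inf, ui = -Inf)
  upper <- c(dH = Inf, tm = max(tK), fs = Inf, fi = Inf, us = Inf, ui = Inf)

  nls_fit <- tryCatch(
    suppressWarnings(minpack.lm::nlsLM(
      absorbance ~ .melt_model(tK, dH, tm, fs, fi, us, ui, ref_temp = ref),
      data = dat, start = start, lower = lower, upper = upper,
      control = minpack.lm::nls.lm.control(maxiter = max_iter)
    )),
    error = function(e) e
  )

  if (inherits(nls_fit, "error")) {
    return(new_melt_fit(
      params = init, param_sd = setNames(rep(NA_real_, 6), names(start)),
      residual_sd = NA_real_, converged = FALSE, n_iter = NA_integer_,
      warnings = c(warnings, paste("solver error:", conditionMessage(nls_fit))),
      data = curve, cov = NULL
    ))
  }

  est <- coef(nls_fit)
  converged <- isTRUE(nls_fit$convInfo$isConv)
  # The model is exactly invariant under (dH, baselines) -> (-dH, swapped
  # baselines): f(T; -dH) = 1 - f(T; dH). Canonicalize to the hairpin
  # convention (folded state at low temperature, dH < 0); a genuinely
  # non-hyperchromic curve then surfaces through the hyperchromicity warning.
  mirrored <- est[["dH"]] > 0
  n_iter <- nls_fit$convInfo$finIter %||% NA_integer_
  if (!converged) warnings <- c(warnings, "solver did not converge")

  sm <- tryCatch(summary(nls_fit), error = function(e) NULL)
  if (is.null(sm)) {
    param_sd <- setNames(rep(NA_real_, length(est)), names(est))
    residual_sd <- sqrt(sum(stats::resid(nls_fit)^2) / (nrow(dat) - length(est)))
    warnings <- c(warnings, "covariance singular: standard errors unavailable")
    covm <- NULL
  } else {
    param_sd <- sm$coefficients[, "Std. Error"]
    residual_sd <- sm$sigma
    covm <- sm$cov.unscaled * sm$sigma^2
  }

  if (mirrored) {
    swap <- c("dH", "tm", "us", "ui", "fs", "fi") # fs<->us, fi<->ui
    est <- setNames(est[swap], names(est))
    est[["dH"]] <- -est[["dH"]]
    param_sd <- setNames(param_sd[swap], names(param_sd))
    if (!is.null(covm)) {
      covm <- covm[swap, swap]
      dimnames(covm) <- list(names(est), names(est))
      covm["dH", ] <- -covm["dH", ]
      covm[, "dH"] <- -covm[, "dH"]
    }
    warnings <- c(warnings,
                  "mirrored optimum (positive dH) canonicalized by negating dH and swapping baselines")
  }

  edge <- 5 # degC; tm this close to a range end leaves a baseline poorly determined
  tm_C <- kelvin_to_celsius(est[["tm"]])
  if (tm_C < min(curve$temperature_C) + edge || tm_C > max(curve$temperature_C) - edge) {
    warnings <- c(warnings,
                  sprintf("tm (%.1f degC) within %g degC of the observed range end", tm_C, edge))
  }

  params <- withCallingHandlers(
    two_state_params(
      dH = est[["dH"]], tm = est[["tm"]],
      folded_slope = est[["fs"]], folded_intercept = est[["fi"]],
      unfolded_slope = est[["us"]], unfolded_intercept = est[["ui"]],
      ref_temp = ref
    ),
    warning = function(w) {
      warnings <<- c(warnings, conditionMessage(w))
      invokeRestart("muffleWarning")
    }
  )

  new_melt_fit(params = params, param_sd = param_sd, residual_sd = residual_sd,
               converged = converged, n_iter = n_iter, warnings = warnings,
               data = curve, cov = covm)
}

new_melt_fit <- function(params, param_sd, residual_sd, converged, n_iter,
                         warnings, data, cov) {
  structure(
    list(params = params, param_sd = param_sd, residual_sd = residual_sd,
         converged = converged, n_iter = n_iter, warnings = warnings,
         data = data, cov = cov),
    class = "melt_fit"
  )
}

#' @export
print.melt_fit <- function(x, ...) {
  th <- derive_thermo(x$params$dH, x$params$tm)
  cat(sprintf("Two-state melt fit (%s, %d points)\n",
              if (x$converged) "converged" else "NOT converged", nrow(x$data)))
  cat(sprintf("  tm   %7.2f degC    dH %8.2f kcal/mol\n", th$tm_celsius, th$dH))
  cat(sprintf("  dS   %7.1f e.u.    dG37 %6.3f kcal/mol\n", th$dS, th$dG37))
  cat(sprintf("  residual SD %.2e AU\n", x$residual_sd))
  if (length(x$warnings)) cat("  warnings:", paste(x$warnings, collapse = "; "), "\n")
  invisible(x)
}

#' Brute-force grid-search fit with profiled baselines
#'
#' An independent estimator of the transition parameters used to validate the
#' nonlinear least-squares route: for every (enthalpy, melting temperature)
#' pair on a regular grid, the four baseline coefficients — in which the model
#' is linear once the folded fraction is fixed — are profiled out by ordinary
#' linear least squares, and the grid point with the smallest residual sum of
#' squares wins. Deliberately shares no solver machinery with
#' [fit_two_state()].
#'
#' The default enthalpy window spans the physically plausible hairpin range
#' (-80 to -5 kcal mol^-1); the melting-temperature window defaults to
#' +/- 15 degC around the data-driven [initial_guess()] (clipped to the
#' observed range; wide enough to cover the peak-position bias of very broad
#' transitions), which keeps the tm quantization fine enough that the
#' induced shift along the strongly correlated enthalpy--tm valley stays
#' below one enthalpy cell.
#'
#' @param curve tibble with `temperature_C`, `absorbance`.
#' @param dH_range enthalpy search interval, kcal mol^-1.
#' @param tm_range melting-temperature search interval, degC.
#' @param n_grid grid points per axis.
#' @return one-row tibble: `dH`, `tm_celsius`, `rss`, and the grid cell sizes
#'   `dH_step`, `tm_step` that bound the resolution of the estimate.
#' @export
grid_fit_two_state <- function(curve, dH_range = NULL, tm_range = NULL,
                               n_grid = 200) {
  .validate_curve(curve)
  tK <- celsius_to_kelvin(curve$temperature_C)
  a <- curve$absorbance
  ref <- min(tK)
  dT <- tK - ref
  dH_range <- dH_range %||% c(-80, -5)
  if (is.null(tm_range)) {
    guess <- suppressWarnings(initial_guess(curve))
    tm_guess_C <- kelvin_to_celsius(guess$tm)
    tm_range <- pmin(pmax(tm_guess_C + c(-15, 15), min(curve$temperature_C)),
                     max(curve$temperature_C))
  }
  dH_grid <- seq(dH_range[1], dH_range[2], length.out = n_grid)
  tm_grid <- celsius_to_kelvin(seq(tm_range[1], tm_range[2], length.out = n_grid))
  Rg <- thermo_constants()$R_gas

  best <- list(rss = Inf, dH = NA_real_, tm = NA_real_)
  for (tm in tm_grid) {
    inv_diff <- 1 / tK - 1 / tm
    for (dH in dH_grid) {
      f <- plogis(-(dH / Rg) * inv_diff)
      X <- cbind(f, f * dT, 1 - f, (1 - f) * dT)
      fit <- stats::.lm.fit(X, a)
      rss <- sum(fit$residuals^2)
      if (rss < best$rss) best <- list(rss = rss, dH = dH, tm = tm)
    }
  }
  tibble::tibble(
    dH = best$dH, tm_celsius = kelvin_to_celsius(best$tm), rss = best$rss,
    dH_step = diff(dH_grid[1:2]), tm_step = diff(kelvin_to_celsius(tm_grid[1:2]))
  )
}

#' Baseline-normalized melt curve (fraction unfolded)
#'
#' Rescales an absorbance curve with a converged fit's baselines:
#' `(A - B_folded) / (B_unfolded - B_folded)`, i.e. the apparent fraction
#' unfolded, approximately 0 well below the melting temperature and 1 well
#' above it (noise may push values slightly outside `[0, 1]`).
#'
#' @param curve tibble with `temperature_C`, `absorbance`.
#' @param fit a converged `melt_fit` for that curve.
#' @return the curve tibble plus a `fraction_unfolded` column.
#' @export
normalized_curve <- function(curve, fit) {
  stopifnot(inherits(fit, "melt_fit"))
  if (!fit$converged) {
    abort("Normalization requires a converged fit.", class = "tetramelt_fit_error")
  }
  .validate_curve(curve)
  p <- fit$params
  dT <- celsius_to_kelvin(curve$temperature_C) - p$ref_temp
  bf <- p$folded_intercept + p$folded_slope * dT
  bu <- p$unfolded_intercept + p$unfolded_slope * dT
  if (any(abs(bu - bf) < 1e-8)) {
    abort("Baselines coincide within the observed range: normalization is degenerate.",
          class = "tetramelt_degenerate_error")
  }
  dplyr::mutate(tibble::as_tibble(curve),
                fraction_unfolded = (.data$absorbance - bf) / (bu - bf))
}

#' Fit every curve in a long cohort table
#'
#' Maps [fit_two_state()] over each `sample_id` group of a long melt-curve
#' table (as produced by [simulate_cohort()] or assembled from
#' [read_melt_file()] calls) and returns one row per curve with the condition
#' metadata, the derived thermodynamics, fit standard errors and diagnostics.
#' Curves that fail to converge are retained with `converged = FALSE` so the
#' caller can exclude them from aggregation.
#'
#' @param curves long tibble: metadata columns, `sample_id`, `temperature_C`,
#'   `absorbance`.
#' @param max_iter passed to [fit_two_state()].
#' @return tibble with one row per `sample_id`: metadata, `dH`, `dS`,
#'   `tm_celsius`, `dG37`, `dH_se`, `tm_se` (degC scale), `residual_sd`,
#'   `converged`, `n_warnings`.
#' @export
fit_melt_curves <- function(curves, max_iter = 200) {
  stopifnot("sample_id" %in% names(curves))
  meta_cols <- intersect(
    c("sequence", "polymer", "stem", "closing_pair", "cosolute", "conc_wv",
      "replicate", "wavelength_nm"),
    names(curves)
  )
  curves |>
    tidyr::nest(curve = c("temperature_C", "absorbance"),
                .by = dplyr::all_of(c("sample_id", meta_cols))) |>
    dplyr::mutate(fit = purrr::map(.data$curve, function(cv) {
      ft <- suppressWarnings(fit_two_state(cv, max_iter = max_iter))
      th <- derive_thermo(ft$params$dH, ft$params$tm)
      tibble::tibble(
        dH = th$dH, dS = th$dS, tm_celsius = th$tm_celsius, dG37 = th$dG37,
        dH_se = unname(ft$param_sd["dH"]), tm_se = unname(ft$param_sd["tm"]),
        residual_sd = ft$residual_sd, converged = ft$converged,
        n_warnings = length(ft$warnings)
      )
    })) |>
    dplyr::select(-"curve") |>
    tidyr::unnest("fit")
}
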