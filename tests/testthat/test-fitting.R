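test_that("initial guess lands near the generating parameters on a clean curve", {
  cv <- std_curve()
  g <- initial_guess(cv)
  expect_lt(abs(kelvin_to_celsius(g$tm) - 67.9), 1)
  expect_lt(g$dH, 0)
  # baselines from the curve ends should be close to the generating ones
  expect_equal(g$folded_intercept, default_baselines()$folded_intercept,
               tolerance = 0.01)
})

test_that("a flat curve raises a no-transition error", {
  flat <- tibble::tibble(temperature_C = seq(10, 90, 0.5),
                         absorbance = 0.7 + 2e-4 * seq(10, 90, 0.5))
  expect_error(initial_guess(flat), class = "tetramelt_no_transition_error")
})

test_that("an unfolding-oriented curve yields a positive enthalpy guess with a warning", {
  bl <- default_baselines()
  p_rev <- suppressWarnings(two_state_params(
    dH = -42.2, tm = celsius_to_kelvin(55),
    folded_slope = bl$unfolded_slope, folded_intercept = bl$unfolded_intercept,
    unfolded_slope = bl$folded_slope, unfolded_intercept = bl$folded_intercept,
    ref_temp = celsius_to_kelvin(10)
  ))
  cv <- simulate_melt_curve(p_rev, noise_sd = 0)
  cnds <- list()
  g <- withCallingHandlers(
    initial_guess(cv),
    warning = function(w) {
      cnds[[length(cnds) + 1]] <<- w
      invokeRestart("muffleWarning")
    }
  )
  expect_true(any(vapply(cnds, inherits, logical(1), "tetramelt_orientation_warning")))
  expect_gt(g$dH, 0)
})

test_that("a noiseless curve is recovered to numerical precision", {
  p <- std_params()
  fit <- fit_two_state(simulate_melt_curve(p, noise_sd = 0))
  expect_true(fit$converged)
  expect_equal(fit$params$dH, p$dH, tolerance = 1e-6)
  expect_equal(fit$params$tm, p$tm, tolerance = 1e-6)
  expect_equal(fit$params$folded_intercept, p$folded_intercept, tolerance = 1e-6)
  expect_equal(fit$params$unfolded_intercept, p$unfolded_intercept, tolerance = 1e-6)
})

test_that("noisy-curve estimates fall within three standard errors of truth", {
  p <- std_params()
  fit <- suppressWarnings(fit_two_state(simulate_melt_curve(p, noise_sd = 0.002, seed = 42)))
  expect_true(fit$converged)
  expect_lt(abs(fit$params$dH - p$dH), 3 * fit$param_sd[["dH"]])
  expect_lt(abs(fit$params$tm - p$tm), 3 * fit$param_sd[["tm"]])
})

test_that("fits are equivariant under shifting and scaling of the absorbance axis", {
  cv <- std_curve(noise_sd = 0.002, seed = 13)
  f0 <- suppressWarnings(fit_two_state(cv))

  shifted <- dplyr::mutate(cv, absorbance = absorbance + 0.25)
  fs <- suppressWarnings(fit_two_state(shifted))
  expect_equal(fs$params$dH, f0$params$dH, tolerance = 1e-4)
  expect_equal(fs$params$tm, f0$params$tm, tolerance = 1e-6)
  expect_equal(fs$params$folded_intercept, f0$params$folded_intercept + 0.25,
               tolerance = 1e-4)

  scaled <- dplyr::mutate(cv, absorbance = absorbance * 3)
  fc <- suppressWarnings(fit_two_state(scaled))
  expect_equal(fc$params$dH, f0$params$dH, tolerance = 1e-4)
  expect_equal(fc$params$tm, f0$params$tm, tolerance = 1e-6)
  expect_equal(fc$params$unfolded_intercept, 3 * f0$params$unfolded_intercept,
               tolerance = 1e-4)
  expect_equal(fc$residual_sd, 3 * f0$residual_sd, tolerance = 1e-3)
})

test_that("the fit agrees with the profiled grid-search oracle", {
  set.seed(23)
  for (i in 1:3) {
    dH <- runif(1, -45, -20)
    tm_C <- runif(1, 35, 65)
    cv <- std_curve(dH, tm_C, noise_sd = 0.002, seed = 1000 + i)
    nls_fit <- suppressWarnings(fit_two_state(cv))
    grid <- grid_fit_two_state(cv, n_grid = 200)
    expect_lt(abs(nls_fit$params$dH - grid$dH), grid$dH_step)
    expect_lt(abs(kelvin_to_celsius(nls_fit$params$tm) - grid$tm_celsius),
              grid$tm_step)
  }
})

test_that("a mirrored (positive-dH) optimum is canonicalized to the hairpin convention", {
  cv <- std_curve(noise_sd = 0.002, seed = 77)
  bl <- default_baselines()
  mirrored_init <- suppressWarnings(two_state_params(
    dH = 42.2, tm = celsius_to_kelvin(67.9),
    folded_slope = bl$unfolded_slope, folded_intercept = bl$unfolded_intercept,
    unfolded_slope = bl$folded_slope, unfolded_intercept = bl$folded_intercept,
    ref_temp = celsius_to_kelvin(10)
  ))
  fit <- suppressWarnings(fit_two_state(cv, init = mirrored_init))
  expect_true(fit$converged)
  expect_lt(fit$params$dH, 0)
  expect_equal(fit$params$dH, -42.2, tolerance = 0.15)
  expect_true(any(grepl("mirrored", fit$warnings)))
})

test_that("non-convergence is reported in the result, not thrown", {
  cv <- std_curve(noise_sd = 0.002, seed = 8)
  fit <- suppressWarnings(fit_two_state(cv, max_iter = 1))
  expect_s3_class(fit, "melt_fit")
  expect_false(fit$converged)
  expect_true(length(fit$warnings) > 0)
})

test_that("normalization gives fraction unfolded: ~0 below, 0.5 at tm, ~1 above", {
  p <- std_params()
  cv <- simulate_melt_curve(p, noise_sd = 0)
  fit <- fit_two_state(cv)
  nc <- normalized_curve(cv, fit)
  f <- fraction_folded(celsius_to_kelvin(cv$temperature_C), p$dH, p$tm)
  expect_equal(nc$fraction_unfolded, 1 - f, tolerance = 1e-6)
  low_T <- nc$fraction_unfolded[cv$temperature_C < 30]
  expect_lt(mean(abs(low_T)), 0.01)
  at_tm <- which.min(abs(cv$temperature_C - kelvin_to_celsius(p$tm)))
  expect_equal(nc$fraction_unfolded[at_tm], 0.5, tolerance = 0.01)
})

test_that("normalization refuses coincident baselines", {
  cv <- std_curve()
  fit <- fit_two_state(cv)
  fit$params$unfolded_intercept <- fit$params$folded_intercept
  fit$params$unfolded_slope <- fit$params$folded_slope
  expect_error(normalized_curve(cv, fit), class = "tetramelt_degenerate_error")
})

test_that("batch fitting keeps metadata and yields one row per curve", {
  cohort <- simulate_cohort(
    conditions = gaaa_conditions()[c(1, 2), ],
    noise_sd = 0.001, n_replicates = 2, seed = 5
  )
  fits <- fit_melt_curves(cohort)
  expect_equal(nrow(fits), 4)
  expect_setequal(
    c("sample_id", "sequence", "polymer", "stem", "closing_pair", "cosolute",
      "conc_wv", "replicate", "wavelength_nm") ,
    setdiff(names(fits), c("dH", "dS", "tm_celsius", "dG37", "dH_se", "tm_se",
                           "residual_sd", "converged", "n_warnings"))
  )
  expect_true(all(fits$converged))
})

test_that("curve validation rejects malformed input", {
  expect_error(fit_two_state(tibble::tibble(temperature_C = 1:5, absorbance = 1:5)),
               class = "tetramelt_curve_error")
  bad <- tibble::tibble(temperature_C = c(1:9, 9), absorbance = rnorm(10))
  expect_error(fit_two_state(bad), class = "tetramelt_curve_error")
})
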