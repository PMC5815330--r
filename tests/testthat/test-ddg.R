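test_that("cosolute destabilization reproduces published comparisons", {
  # stable stem-1 CG hairpin in 40% PEG 200: 1.82 +/- 0.06
  d <- ddg_cosolute(-2.00, -3.82, 0.05, 0.04)
  expect_equal(d$estimate, 1.82)
  expect_equal(round(d$sd, 2), 0.06)
  # same hairpin in 40% PEG 8000: 0.89 +/- 0.07
  d8 <- ddg_cosolute(-2.93, -3.82, 0.06, 0.04)
  expect_equal(d8$estimate, 0.89)
  expect_equal(round(d8$sd, 2), 0.07)
  # self-difference: zero with sqrt(2)-inflated spread
  d0 <- ddg_cosolute(-2.5, -2.5, 0.05, 0.05)
  expect_equal(d0$estimate, 0)
  expect_equal(d0$sd, sqrt(2) * 0.05)
  expect_error(ddg_cosolute(-2, -3.82, sequence_cosolute = "1cg", sequence_none = "2cg"),
               class = "tetramelt_pairing_error")
})

test_that("closing-base-pair comparison reproduces published differences", {
  d <- ddg_gc_cg(-2.19, -3.82, 0.05, 0.04) # stem 1, no cosolute: 1.63 +/- 0.06
  expect_equal(d$estimate, 1.63)
  expect_equal(round(d$sd, 2), 0.06)
  d2 <- ddg_gc_cg(-0.87, -2.80, 0.03, 0.05) # DNA triloop: 1.93 +/- 0.06
  expect_equal(d2$estimate, 1.93)
  expect_equal(round(d2$sd, 2), 0.06)
  expect_equal(ddg_gc_cg(-1.5, -1.5)$estimate, 0)
  expect_error(ddg_gc_cg(-2, -3, pair_gc = "CG", pair_cg = "CG"),
               class = "tetramelt_pairing_error")
})

test_that("stacking correction isolates the loop term with unchanged spread", {
  l <- ddg_loop(1.63, 0.06)
  expect_equal(l$estimate, 1.47)
  expect_equal(l$sd, 0.06)
  expect_equal(ddg_loop(1.52, 0.06)$estimate, 1.36)
  expect_equal(ddg_loop(0.16)$estimate, 0)
})

test_that("cosolute effect on the loop gap matches published values in the reported convention", {
  d <- dddg_loop_cosolute(0.84, 1.47, 0.07, 0.06) # stem 1, PEG 200
  expect_equal(d$estimate, 0.63)
  expect_equal(d$signed, -0.63)
  expect_equal(round(d$sd, 2), 0.09)
  d2 <- dddg_loop_cosolute(1.17, 1.77, 0.05, 0.06) # DNA triloop, PEG 200
  expect_equal(d2$estimate, 0.60)
  expect_equal(round(d2$sd, 2), 0.08)
  expect_equal(dddg_loop_cosolute(1.0, 1.0)$estimate, 0)
  expect_error(dddg_loop_cosolute(0.8, 1.4, stem_cosolute = "1", stem_none = "2"),
               class = "tetramelt_pairing_error")
})

test_that("gap reduction percent behaves and coheres in sign with the reported gap change", {
  expect_equal(gap_reduction_percent(0.84, 1.47), 100 * (1.47 - 0.84) / 1.47)
  expect_gt(gap_reduction_percent(0.84, 1.47), 40)
  expect_equal(gap_reduction_percent(1.2, 1.2), 0)
  expect_equal(gap_reduction_percent(0, 1.47), 100)
  expect_error(gap_reduction_percent(0.5, 0), class = "tetramelt_domain_error")

  set.seed(41)
  for (i in 1:20) {
    lc <- runif(1, -2, 2); ln <- runif(1, 0.1, 2)
    expect_equal(gap_reduction_percent(lc, ln) > 0,
                 dddg_loop_cosolute(lc, ln)$estimate > 0)
  }
})

test_that("m-value requires an explicit molality and divides through", {
  expect_error(m_value(1.82), class = "tetramelt_molality_error")
  expect_error(m_value(1.82, NA), class = "tetramelt_molality_error")
  expect_error(m_value(1.82, -2), class = "tetramelt_domain_error")
  expect_equal(m_value(1.82, 3.1), 1.82 / 3.1)
  expect_equal(m_value(0, 3.1), 0)
  expect_equal(m_value(-0.63, 1), -0.63)
})

test_that("concentration regression recovers exact lines and resists shifts", {
  pts <- tibble::tibble(conc_wv = c(0, 10, 20, 40), dG37 = 0.05 * c(0, 10, 20, 40) - 3.8)
  r <- conc_regression(pts)
  expect_equal(r$slope, 0.05)
  expect_equal(r$intercept, -3.8)
  expect_equal(r$r_squared, 1)

  # two-point endpoint line through the published 0% and 40% free energies
  r2 <- conc_regression(tibble::tibble(conc_wv = c(0, 40), dG37 = c(-3.82, -2.00)))
  expect_equal(r2$slope, 0.0455)
  expect_equal(r2$intercept, -3.82)

  shifted <- dplyr::mutate(pts, dG37 = dG37 + 1.3)
  expect_equal(conc_regression(shifted)$slope, r$slope)

  expect_error(conc_regression(tibble::tibble(conc_wv = c(10, 10), dG37 = c(1, 2))),
               class = "tetramelt_singular_design_error")
})

test_that("error propagation is additive in variance for every subtraction", {
  set.seed(51)
  for (i in 1:25) {
    a <- runif(1, -4, 1); b <- runif(1, -4, 1)
    sa <- runif(1, 0, 0.2); sb <- runif(1, 0, 0.2)
    expect_equal(ddg_cosolute(a, b, sa, sb)$sd^2, sa^2 + sb^2)
    expect_equal(ddg_gc_cg(a, b, sa, sb)$sd^2, sa^2 + sb^2)
    expect_equal(dddg_loop_cosolute(a, b, sa, sb)$sd^2, sa^2 + sb^2)
    expect_equal(ddg_loop(a, sa)$sd, sa)
  }
})

test_that("the ladder is algebraically consistent: loop + stacking + CG free energy = GC free energy", {
  set.seed(61)
  for (i in 1:20) {
    g_gc <- runif(1, -3, 1); g_cg <- runif(1, -4, 0)
    loop <- ddg_loop(ddg_gc_cg(g_gc, g_cg)$estimate)$estimate
    expect_equal(loop + 0.16 + g_cg, g_gc, tolerance = 1e-12)
  }
})

test_that("the full ladder on the published summary reproduces its derived columns", {
  lad <- ddg_ladder(gaaa_conditions())
  expect_equal(nrow(lad), 14)
  cell <- function(seq, cos) lad[lad$sequence == seq & lad$cosolute == cos, ]

  expect_equal(round(cell("1gc", "none")$ddg_gc_cg, 2), 1.63)
  expect_equal(round(cell("1gc", "none")$ddg_loop, 2), 1.47)
  expect_equal(round(cell("2gc", "none")$ddg_loop, 2), 1.36)
  expect_equal(round(cell("d2gc", "none")$ddg_gc_cg, 2), 1.93)
  expect_equal(round(cell("1cg", "PEG200")$ddg_cosolute, 2), 1.82)
  expect_equal(round(cell("1gc", "PEG8000")$ddg_cosolute, 2), 0.32)
  expect_equal(round(cell("1gc", "PEG200")$dddg_loop, 2), 0.63)
  expect_equal(round(cell("d2gc", "PEG200")$dddg_loop, 2), 0.60)
  # CG rows and no-cosolute rows carry no comparison where undefined
  expect_true(is.na(cell("1cg", "none")$ddg_gc_cg))
  expect_true(is.na(cell("1cg", "none")$ddg_cosolute))
  # gap reductions exceed 40% for both RNA stems in the osmolyte background
  expect_gt(cell("1gc", "PEG200")$gap_reduction_pct, 40)
  expect_gt(cell("2gc", "PEG200")$gap_reduction_pct, 40)
})

test_that("ladder input validation catches missing metadata", {
  expect_error(ddg_ladder(tibble::tibble(sequence = "1cg", dG37 = -3.8)),
               class = "tetramelt_pairing_error")
})
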