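test_that("OLS trend matches hand-computed fits", {
  ft <- fit_linear_trend(c(0, 1, 2), c(0, 1, 1))
  expect_equal(ft$slope, 0.5)
  expect_equal(ft$intercept, 1 / 6, tolerance = 1e-12)
  expect_equal(ft$r_squared, 0.75)
  # perfectly collinear
  ft2 <- fit_linear_trend(1:10, 2 - 0.3 * (1:10))
  expect_equal(ft2$r_squared, 1)
  expect_lt(ft2$p_value, 1e-6)
  # constant response: no trend, not an error
  ft3 <- fit_linear_trend(1:6, rep(4, 6))
  expect_equal(ft3$r_squared, 0)
  expect_equal(ft3$p_value, 1)
  expect_false(ft3$significant)
  expect_error(fit_linear_trend(rep(1, 5), 1:5), "constant")
  expect_error(fit_linear_trend(1:2, 1:2), "at least 3")
})

test_that("R-squared is affine invariant; slope scales with units", {
  set.seed(5)
  x <- rep(c(5, 10, 15, 20, 25), each = 3)
  y <- 1 - 0.03 * x + stats::rnorm(15, sd = 0.05)
  f0 <- fit_linear_trend(x, y)
  f_shift <- fit_linear_trend(x + 273.15, y)   # C -> K offset
  expect_equal(f_shift$slope, f0$slope, tolerance = 1e-12)
  expect_equal(f_shift$r_squared, f0$r_squared, tolerance = 1e-12)
  f_aff <- fit_linear_trend(2 * x - 3, 10 * y + 4)
  expect_equal(f_aff$r_squared, f0$r_squared, tolerance = 1e-12)
  expect_equal(f_aff$slope, 10 * f0$slope / 2, tolerance = 1e-12)
})

test_that("Spearman correlation matches rank arithmetic and the oracle", {
  expect_equal(spearman_assoc(1:8, exp(1:8))$rho, 1)      # monotone -> 1
  expect_equal(spearman_assoc(c(1, 2, 3), c(3, 1, 2))$rho, -0.5)
  # rank invariance: any monotone transform leaves rho unchanged
  set.seed(9)
  x <- stats::runif(20)
  y <- stats::rnorm(20)
  expect_equal(spearman_assoc(x, y)$rho, spearman_assoc(exp(x), y)$rho)
  # cross-check rho and t-approximation p against the base-R oracle
  for (i in 1:5) {
    a <- stats::rnorm(15)
    b <- 0.5 * a + stats::rnorm(15)
    got <- spearman_assoc(a, b)
    ref <- suppressWarnings(stats::cor.test(a, b, method = "spearman",
                                            exact = FALSE))
    expect_equal(got$rho, unname(ref$estimate), tolerance = 1e-12)
    expect_equal(got$p_value, ref$p.value, tolerance = 1e-8)
  }
  expect_true(is.na(spearman_assoc(c(1, 1, 1), 1:3)$rho))
})

test_that("ANOVA + Tukey reproduce the hand example and k = 2 equivalence", {
  at <- anova_tukey(c(1, 2, 3, 4, 5, 6), rep(c("a", "b"), each = 3))
  expect_equal(at$f_statistic, 13.5)
  expect_equal(at$df, c(1L, 4L))
  expect_equal(at$p_value, stats::pf(13.5, 1, 4, lower.tail = FALSE))
  # with two groups the Tukey-adjusted p equals the pooled two-sample p
  tt <- stats::t.test(c(4, 5, 6), c(1, 2, 3), var.equal = TRUE)
  expect_lt(abs(at$comparisons$p_adj - tt$p.value), 1e-6)
  # identical groups: F ~ 0, nothing significant
  at0 <- anova_tukey(rep(c(1, 2, 3), 2), rep(c("a", "b"), each = 3))
  expect_lt(abs(at0$f_statistic), 1e-10)
  expect_false(any(at0$comparisons$significant))
  # zero variance everywhere -> flagged degenerate
  atd <- anova_tukey(rep(c(1, 5), each = 3), rep(c("a", "b"), each = 3))
  expect_true(atd$degenerate)
  expect_true(is.na(atd$f_statistic))
})

test_that("trend_report recovers injected signs and skips missing responses", {
  spec <- strain_sim_spec(
    "t", c("i-C15", "ai-C15", "n-C15", "i-C17", "ai-C17", "n-C17"),
    baseline = c(40, 15, 10, 20, 5, 10),
    class_slopes = c(iso = 0.03, anteiso = -0.03, normal = 0),
    noise_sd = 0.04)
  series <- generate_series(spec, seed = 301)
  tr <- trend_report(series)
  aon <- tr[tr$response == "anteiso_over_normal", ]
  expect_lt(aon$slope, 0)
  expect_true(aon$significant)
  ioa <- tr[tr$response == "iso_over_anteiso", ]
  expect_gt(ioa$slope, 0)
  expect_true(ioa$significant)
  expect_equal(unique(tr$n), 15)
  # a response missing everywhere is skipped with a warning (RAN15 without
  # a normal C15 homologue)
  spec2 <- strain_sim_spec("t2", c("i-C15", "ai-C15", "n-C16"),
                           baseline = c(50, 30, 20),
                           noise_sd = 0.04)
  expect_warning(
    expect_warning(tr2 <- trend_report(generate_series(spec2, seed = 5)),
                   "RAN15"),
    "RAN17")
  expect_false("RAN15" %in% tr2$response)
})

test_that("permuted responses show null-level R-squared", {
  set.seed(41)
  x <- rep(c(5, 10, 15, 20, 25), each = 3)
  y <- 2 - 0.1 * x + stats::rnorm(15, sd = 0.1)
  r2 <- replicate(200, fit_linear_trend(x, sample(y))$r_squared)
  # E[R^2] under the null is 1/(n-1) ~ 0.071 for n = 15
  expect_lt(mean(r2), 0.15)
  expect_gt(fit_linear_trend(x, y)$r_squared, 0.9)
})

test_that("calibration inversion is exact on the line and refuses noise-only fits", {
  x <- rep(c(5, 10, 15, 20, 25), each = 3)
  set.seed(13)
  y <- 2 - 0.1 * x + stats::rnorm(15, sd = 0.01)
  ft <- fit_linear_trend(x, y)
  inv <- invert_calibration(ft, 1)
  expect_equal(inv$x_hat, (1 - ft$intercept) / ft$slope)
  expect_equal(inv$x_hat, 10, tolerance = 0.5)
  expect_lt(inv$lower, inv$x_hat)
  expect_gt(inv$upper, inv$x_hat)
  inv0 <- invert_calibration(ft, ft$intercept)
  expect_equal(inv0$x_hat, 0)
  # non-significant fit refused
  yn <- stats::rnorm(15)
  ftn <- fit_linear_trend(x, yn)
  if (!ftn$significant) expect_error(invert_calibration(ftn, 0), "significant")
  # Monte-Carlo: median inversion error < 2 C at the stated noise level
  err <- replicate(200, {
    yy <- 2 - 0.03 * x + stats::rnorm(15, sd = 0.01)
    f <- fit_linear_trend(x, yy)
    abs(invert_calibration(f, 2 - 0.03 * 12)$x_hat - 12)
  })
  expect_lt(stats::median(err), 2)
})
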