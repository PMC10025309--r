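test_that("RIAN arithmetic matches hand-computed values", {
  expect_equal(rian_from_totals(50, 25, 25), -log10(3), tolerance = 1e-12)
  expect_equal(round(rian_from_totals(50, 25, 25), 3), -0.477)
  expect_equal(rian_from_totals(30, 20, 50), 0)    # I + A = N
  expect_true(is.na(rian_from_totals(50, 50, 0)))  # N = 0 undefined
  expect_true(is.na(rian_from_totals(0, 0, 100)))  # I + A = 0 undefined
  expect_error(rian_from_totals(-1, 0, 1), "non-negative")
})

test_that("RIAN is antisymmetric and monotone", {
  set.seed(11)
  for (i in 1:40) {
    ia <- stats::runif(1, 0.1, 99)
    n <- stats::runif(1, 0.1, 99)
    # swapping the roles of (I+A) and N flips the sign
    expect_equal(rian_from_totals(ia, 0, n), -rian_from_totals(n, 0, ia),
                 tolerance = 1e-12)
    # with N fixed, RIAN strictly decreases as I+A grows
    expect_lt(rian_from_totals(ia * 1.5, 0, n), rian_from_totals(ia, 0, n))
  }
})

test_that("RAN ratios follow the undefined-on-zero rule", {
  p <- make_profile(c("ai-C15" = 25, "n-C15" = 25, "ai-C17" = 30,
                      "n-C17" = 20))
  expect_equal(ran15(p), 1.0)
  expect_equal(ran17(p), 1.5)
  # normal homologue undetected -> undefined, like strain B's printed n.d.
  m <- fa_measurements(c("ai-C15", "n-C15", "i-C15"), c(40, NA, 60),
                       default_3oh = TRUE)
  p_nd <- sample_profile(m, check_closure = FALSE)
  expect_true(is.na(ran15(p_nd)))
  # monotone in the anteiso numerator
  p_hi <- make_profile(c("ai-C15" = 40, "n-C15" = 25, "i-C15" = 35))
  p_lo <- make_profile(c("ai-C15" = 20, "n-C15" = 25, "i-C15" = 55))
  expect_gt(ran15(p_hi), ran15(p_lo))
})

test_that("branching ratios and the basis guard behave", {
  br <- branching_ratios(make_profile(c("i-C15" = 30, "ai-C15" = 30,
                                        "n-C15" = 30, "n-C17" = 10)))
  expect_equal(unname(br["iso_over_anteiso"]), 1)
  expect_equal(unname(br["iso_over_normal"]), 0.75)
  p_fa <- make_profile(c("i-C15" = 60, "16:1" = 40), basis = "total_FAs",
                       default_3oh = FALSE)
  expect_error(rian(p_fa), "total_3OH_FAs")
  expect_error(ran15(p_fa), "total_3OH_FAs")
  expect_error(branching_ratios(p_fa), "total_3OH_FAs")
})

test_that("indices are unit invariant (areas vs closed abundances)", {
  set.seed(23)
  for (i in 1:10) {
    areas <- stats::runif(6, 0.5, 80)
    names(areas) <- c("i-C15", "ai-C15", "n-C15", "i-C17", "ai-C17", "n-C17")
    p_area <- make_profile(areas, value_kind = "peak_area")
    p_norm <- normalize_profile(p_area)
    expect_equal(rian(p_area), rian(p_norm), tolerance = 1e-12)
    expect_equal(ran15(p_area), ran15(p_norm), tolerance = 1e-12)
    expect_equal(branching_ratios(p_area), branching_ratios(p_norm),
                 tolerance = 1e-12)
  }
})

test_that("index_table modes coincide for identical replicates", {
  p5 <- make_profile(c("i-C15" = 60, "ai-C15" = 10, "n-C15" = 30),
                     condition_value = 5)
  p25 <- make_profile(c("i-C15" = 70, "ai-C15" = 5, "n-C15" = 25),
                      condition_value = 25)
  series <- experiment_series(c(rep(list(p5), 3), rep(list(p25), 3)))
  per <- index_table(series, "per_replicate")
  rom <- index_table(series, "ratio_of_means")
  expect_true(all(per$sd[per$n_defined > 1] == 0))
  expect_equal(per$value, rom$value, tolerance = 1e-12)
  # RAN17 is undefined here (no C17 homologues); everything else uses all 3
  expect_equal(per$n_defined[per$index != "RAN17"],
               rep(3, sum(per$index != "RAN17")))
  expect_equal(per$n_defined[per$index == "RAN17"], c(0, 0))
})

test_that("per-replicate ratio means exceed ratio of means under noise", {
  # Jensen: for A/N with lognormal replicate noise in the denominator the
  # mean of per-replicate ratios is >= the ratio of the means (on average).
  set.seed(77)
  a <- stats::rlnorm(2000, log(8), 0.2)
  n <- stats::rlnorm(2000, log(10), 0.2)
  expect_gt(mean(a / n), mean(a) / mean(n))
})

test_that("ratio-of-means RIAN tracks the printed index rows within sd", {
  fx <- load_fixture("table4")
  printed <- c(`5` = -0.92, `10` = -0.97, `15` = -0.99, `20` = -0.85,
               `25` = -0.52)
  sds <- c(0.006, 0.02, 0.15, 0.07, 0.05)
  for (i in seq_along(printed)) {
    lv <- as.numeric(names(printed)[i])
    got <- rian(fixture_aggregate(fx, "temperature_C", lv))
    expect_lt(abs(got - printed[[i]]), sds[i] + 0.005,
              label = paste("RIAN at", lv, "C"))
  }
})

test_that("near-zero RAN denominators are flagged", {
  p <- make_profile(c("ai-C17" = 40, "n-C17" = 0.05, "i-C15" = 59.95))
  is1 <- index_set(p)
  expect_true(is1$ran17_small_denom)
  expect_false(is1$ran15_small_denom)
  expect_gt(is1$RAN17, 100)
})
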