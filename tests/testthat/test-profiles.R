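test_that("normalization closes, is idempotent and scale-invariant", {
  p <- make_profile(c("i-C15" = 2, "ai-C15" = 3, "n-C15" = 5),
                    value_kind = "peak_area")
  np <- normalize_profile(p)
  expect_equal(np$measurements$value, c(20, 30, 50))
  expect_equal(sum(np$measurements$value), 100)
  # single detected compound -> 100%
  p1 <- make_profile(c("i-C15" = 7), value_kind = "peak_area")
  expect_equal(normalize_profile(p1)$measurements$value, 100)
  # property: exact closure, idempotence, scale invariance on random areas
  set.seed(7)
  for (i in 1:25) {
    areas <- stats::runif(6, 0.01, 50)
    names(areas) <- c("i-C14", "i-C15", "ai-C15", "n-C15", "i-C17", "ai-C17")
    q <- normalize_profile(make_profile(areas, value_kind = "peak_area"))
    expect_equal(sum(q$measurements$value), 100, tolerance = 1e-12)
    q2 <- normalize_profile(q)
    expect_equal(q2$measurements$value, q$measurements$value)
    qs <- normalize_profile(make_profile(areas * stats::runif(1, 0.1, 40),
                                         value_kind = "peak_area"))
    expect_equal(qs$measurements$value, q$measurements$value)
  }
})

test_that("normalization preserves n.d. and rejects degenerate input", {
  m <- fa_measurements(c("i-C15", "n-C15"), c(4, NA), default_3oh = TRUE)
  p <- sample_profile(m, value_kind = "peak_area", check_closure = FALSE)
  np <- normalize_profile(p)
  expect_false(np$measurements$detected[2])
  expect_true(is.na(np$measurements$value[2]))
  expect_equal(np$measurements$value[1], 100)
  m0 <- fa_measurements(c("i-C15"), NA_real_, default_3oh = TRUE)
  p0 <- sample_profile(m0, value_kind = "peak_area", check_closure = FALSE)
  expect_error(normalize_profile(p0), "degenerate")
})

test_that("profile invariants are enforced", {
  expect_error(
    fa_measurements(c("i-C15", "iso C_15"), c(1, 2), default_3oh = TRUE),
    "duplicate")
  # total_3OH basis rejects non-hydroxy descriptors
  m <- fa_measurements(c("i-C15", "16:1"), c(50, 50))
  expect_error(sample_profile(m, basis = "total_3OH_FAs"), "3-hydroxylated")
  # closure tolerance on stated relative abundances
  expect_error(make_profile(c("i-C15" = 60, "n-C15" = 30),
                            check_closure = TRUE), "sum to")
  expect_silent(make_profile(c("i-C15" = 60, "n-C15" = 40.3),
                             check_closure = TRUE))
  expect_error(make_profile(c("i-C15" = 120)), "\\[0, 100\\]")
})

test_that("class totals respect branching, detection and carbon scope", {
  p <- make_profile(c("n-C14" = 100))
  expect_equal(class_totals(p), c(iso = 0, anteiso = 0, normal = 100))
  # undetected contributes 0; out-of-scope carbon excluded
  m <- fa_measurements(c("i-C15", "ai-C15", "n-C15", "3-OH n-C9"),
                       c(40, 30, NA, 30), default_3oh = TRUE)
  p2 <- sample_profile(m, check_closure = FALSE)
  expect_equal(class_totals(p2), c(iso = 40, anteiso = 30, normal = 0))
  expect_equal(class_totals(p2, carbon_range = c(2, 40))[["normal"]], 30)
  # non-hydroxy compounds never enter class totals
  m3 <- fa_measurements(c("3-OH i-C15", "16:1"), c(60, 40))
  p3 <- sample_profile(m3, basis = "total_FAs", check_closure = FALSE)
  expect_equal(class_totals(p3), c(iso = 60, anteiso = 0, normal = 0))
})

test_that("replicate aggregation reproduces mean +/- sd cells", {
  ps <- lapply(c(5.0, 5.2, 5.4), function(v)
    make_profile(c("i-C15" = v, "n-C15" = 100 - v)))
  agg <- aggregate_replicates(ps)
  expect_equal(agg$mean[agg$fa_key == "3OH-i-C15:0"], 5.2)
  expect_equal(agg$sd[agg$fa_key == "3OH-i-C15:0"], 0.2)
  expect_identical(attr(agg, "n_replicates"), 3L)
  # single replicate: mean = value, sd undefined
  a1 <- aggregate_replicates(ps[1])
  expect_equal(a1$mean[1], 5.0)
  expect_true(is.na(a1$sd[1]))
  # identical replicates: sd exactly 0
  a3 <- aggregate_replicates(rep(ps[2], 3))
  expect_true(all(a3$sd == 0))
})

test_that("aggregation handles n.d. per policy and rejects mixed bases", {
  p_full <- make_profile(c("i-C15" = 60, "n-C15" = 40))
  m <- fa_measurements(c("i-C15", "n-C15"), c(70, NA), default_3oh = TRUE)
  p_nd <- sample_profile(m, check_closure = FALSE)
  agg <- aggregate_replicates(list(p_full, p_nd))
  expect_equal(agg$mean[agg$fa_key == "3OH-n-C15:0"], 40)  # NA dropped
  expect_equal(agg$n_detected[agg$fa_key == "3OH-n-C15:0"], 1L)
  agg0 <- aggregate_replicates(list(p_full, p_nd), zero_impute = TRUE)
  expect_equal(agg0$mean[agg0$fa_key == "3OH-n-C15:0"], 20)
  p_other <- make_profile(c("i-C15" = 60, "16:1" = 40), basis = "total_FAs",
                          default_3oh = FALSE)
  expect_error(aggregate_replicates(list(p_full, p_other)), "mixed bases")
})

test_that("experiment series validates its invariants", {
  p5 <- make_profile(c("i-C15" = 60, "n-C15" = 40), condition_value = 5)
  p25 <- make_profile(c("i-C15" = 80, "n-C15" = 20), condition_value = 25)
  s <- experiment_series(list(p5, p25))
  expect_equal(s$levels, c(5, 25))
  expect_error(experiment_series(list(p5, p5)), ">= 2 distinct")
  p_other <- make_profile(c("i-C15" = 60, "n-C15" = 40),
                          condition_value = 25, strain_id = "other")
  expect_error(experiment_series(list(p5, p_other)), "share strain_id")
})
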