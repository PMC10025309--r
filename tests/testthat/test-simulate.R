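test_that("the generator is deterministic and closes before flooring", {
  spec <- strain_sim_spec(
    "s", c("i-C15", "ai-C15", "n-C15", "i-C17", "ai-C17", "n-C17"),
    baseline = c(30, 20, 10, 20, 10, 10),
    class_slopes = c(iso = 0.02, anteiso = -0.02, normal = 0),
    noise_sd = 0.05, detection_floor = 0)
  s1 <- generate_series(spec, seed = 99)
  s2 <- generate_series(spec, seed = 99)
  expect_identical(series_to_table(s1), series_to_table(s2))
  s3 <- generate_series(spec, seed = 100)
  expect_false(identical(series_to_table(s1), series_to_table(s3)))
  for (p in s1$profiles) {
    expect_equal(sum(p$measurements$value), 100, tolerance = 1e-9)
  }
  expect_length(s1$profiles, 15)
})

test_that("the zero-noise limit collapses replicates and recovers slopes exactly", {
  spec <- strain_sim_spec(
    "s0", c("i-C15", "ai-C15", "n-C15"),
    baseline = c(50, 30, 20),
    class_slopes = c(iso = 0.05, anteiso = -0.03, normal = 0.01),
    noise_sd = 0, detection_floor = 0)
  s <- generate_series(spec, seed = 1)
  at5 <- Filter(function(p) p$condition_value == 5, s$profiles)
  expect_equal(at5[[1]]$measurements$value, at5[[2]]$measurements$value)
  per <- index_table(s, "per_replicate")
  rom <- index_table(s, "ratio_of_means")
  expect_equal(per$value, rom$value, tolerance = 1e-12)
  rp <- recover_parameters(s)
  expect_equal(rp$slope[rp$ratio == "iso_over_anteiso"], 0.05 - (-0.03),
               tolerance = 1e-8)
  expect_equal(rp$slope[rp$ratio == "anteiso_over_normal"], -0.03 - 0.01,
               tolerance = 1e-8)
})

test_that("the detection floor produces n.d. and degenerate specs error", {
  spec <- strain_sim_spec(
    "sf", c("i-C15", "ai-C15", "n-C15"),
    baseline = c(98, 1.8, 0.2),
    noise_sd = 0.01, detection_floor = 1)
  s <- generate_series(spec, seed = 12)
  nd <- vapply(s$profiles, function(p)
    !p$measurements$detected[p$measurements$fa_key == "3OH-n-C15:0"],
    logical(1))
  expect_true(all(nd))
  expect_error(strain_sim_spec("x", character(0), numeric(0)), "empty")
  expect_error(strain_sim_spec("x", "i-C15", -1), "positive")
})

test_that("the fitted slope responds monotonically to the injected slope", {
  grid <- c(0.01, 0.05, 0.1)
  fitted <- vapply(seq_along(grid), function(i) {
    spec <- strain_sim_spec(
      "sm", c("i-C15", "ai-C15", "n-C15"),
      baseline = c(40, 30, 30),
      class_slopes = c(iso = grid[i], anteiso = 0, normal = 0),
      noise_sd = 0.03)
    rp <- recover_parameters(generate_series(spec, seed = 500 + i))
    rp$slope[rp$ratio == "iso_over_anteiso"]
  }, numeric(1))
  expect_true(all(diff(fitted) > 0))
})

test_that("presets reproduce each strain's observed temperature adaptation", {
  for (st in c("strainA", "strainB", "strainC")) {
    ps <- sim_preset(st, noise_sd = 0.05)
    expect_s3_class(ps, "strain_sim_spec")
    expect_equal(ps$levels, c(5, 10, 15, 20, 25))
    s <- generate_series(ps, seed = 11)
    tr <- suppressWarnings(trend_report(s))
    aon <- tr[tr$response == "anteiso_over_normal", ]
    ioa <- tr[tr$response == "iso_over_anteiso", ]
    expect_lt(aon$slope, 0)
    expect_true(aon$significant)
    expect_gt(ioa$slope, 0)
    expect_true(ioa$significant)
    # generated level means track the printed level means on the log scale
    tb <- c(strainA = "table4", strainB = "table5", strainC = "table6")[[st]]
    fx <- load_fixture(tb)
    gm <- pm <- c()
    for (lv in ps$levels) {
      agg <- aggregate_replicates(
        Filter(function(p) p$condition_value == lv, s$profiles))
      for (lb in ps$labels) {
        cell <- fixture_cell(fx, lb, "temperature_C", lv)
        if (!cell$detected) next
        key <- fa_key(parse_fa_name(lb, default_3oh = TRUE))
        g <- agg$mean[agg$fa_key == key]
        if (is.na(g)) next
        gm <- c(gm, g)
        pm <- c(pm, cell$mean)
      }
    }
    expect_gt(stats::cor(log(gm), log(pm)), 0.95)
  }
})
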