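test_that("record construction enforces the data-model invariants", {
  expect_s3_class(toy_record(), "tc_record")
  expect_error(tc_record(0.5, 1), "at least 2 samples")
  expect_error(tc_record(c(0, 1, 0.5), c(1, 2, 3)),
               "strictly increasing")
  expect_error(tc_record(c(0, 1), c(1, 10), domain = c(-5, 5)),
               "outside declared domain")
  expect_error(tc_record(c(0, Inf), c(1, 2)), "finite")
  # duplicate timestamps: equal values collapse with a warning,
  # differing values are rejected outright
  expect_warning(r <- tc_record(c(0, 1, 1, 2), c(1, 2, 2, 3)),
                 "collapsing")
  expect_equal(r$t, c(0, 1, 2))
  expect_error(suppressWarnings(tc_record(c(0, 1, 1), c(1, 2, 3))),
               "differing values")
  # raw sequences deliberately admit what records reject
  expect_s3_class(tc_sample_seq(c(0, 1, 1), c(1, 2, 3)), "tc_sample_seq")
})

test_that("step-time classification separates equidistant from variable grids", {
  eq <- classify_step_time(toy_record(c(0, .01, .02, .03), rep(0, 4)),
                           rel_tol = 1e-6)
  expect_equal(eq$classification, "equidistant")
  expect_length(eq$delta_ts, 3)
  expect_gt(eq$min_dt, 0)
  vr <- classify_step_time(toy_record(c(0, .01, .025), rep(0, 3)),
                           rel_tol = 1e-6)
  expect_equal(vr$classification, "variable")
  # per-step jitter on an equidistant grid makes it variable
  set.seed(1)
  t <- seq(0, 1, by = 0.01)
  tj <- t + c(0, runif(length(t) - 2, -1e-3, 1e-3), 0)
  expect_equal(classify_step_time(toy_record(tj, numeric(length(tj))))$
                 classification, "variable")
  expect_error(classify_step_time(tc_sample_seq(0, 1)), "at least 2")
})

test_that("resampling any record to a constant grid yields equidistant", {
  g <- fixture_ecg()
  for (tol in c(1e-9, 1e-6, 1e-3)) {
    rs <- tcanon:::resample_curve(g$record, 100)
    r <- toy_record(rs$t, rs$v)
    expect_equal(classify_step_time(r, rel_tol = tol)$classification,
                 "equidistant")
  }
})

test_that("interpolates follow hold/linear semantics and are exact at samples", {
  r <- toy_record(c(0, 1), c(1, 2))
  expect_equal(tc_interpolate(r, 0.5, "hold"), 1)
  expect_equal(tc_interpolate(r, 0.5, "linear"), 1.5)
  expect_error(tc_interpolate(r, -0.1, "linear"), "undefined point")
  expect_error(tc_interpolate(r, -0.1, "hold"), "undefined point")
  expect_error(tc_interpolate(r, 1.2, "linear"), "undefined point")
  # hold is defined beyond the last sample, carrying the last value
  expect_equal(tc_interpolate(r, 5, "hold"), 2)
  # stored samples are returned exactly under both modes
  g <- fixture_ecg()
  idx <- seq(1, length(g$record$t), by = 97)
  for (m in c("hold", "linear"))
    expect_identical(tc_interpolate(g$record, g$record$t[idx], m),
                     g$record$v[idx])
})

test_that("continuity check flags jumps, gaps and hold-interpolate jumps", {
  # same timepoint, values 1 mV apart: a value jump, not continuous
  s <- tc_sample_seq(c(0, 0.002, 0.002, 0.004), c(0, 0, 1, 1))
  cc <- check_continuity(s)
  expect_false(cc$continuous)
  expect_true("no_jumps" %in% cc$failed_conditions)
  # dense clean sine is continuous in linear mode
  t <- seq(0, 1, by = 1 / 500)
  sine <- toy_record(t, sin(2 * pi * 5 * t))
  cc2 <- check_continuity(sine, mode = "linear", max_gap = 0.01)
  expect_true(cc2$continuous)
  expect_length(cc2$failed_conditions, 0)
  # a 2 s hole breaks the sampling-rate/interpolable conditions
  hole <- toy_record(c(t, t + 3), c(sine$v, sine$v))
  cc3 <- check_continuity(hole, max_gap = 0.01)
  expect_false(cc3$continuous)
  expect_true(all(c("sampling_rate", "interpolable") %in%
                    cc3$failed_conditions))
  # the hold interpolate introduces a jump at every value change
  cc4 <- check_continuity(sine, mode = "hold", max_gap = 0.01)
  expect_true("no_jumps" %in% cc4$failed_conditions)
  # non-monotone times beyond duplicates are invalid input
  expect_error(check_continuity(tc_sample_seq(c(0, 1, 0.5), 1:3)),
               "non-monotone")
})

test_that("continuity verdict is monotone in max_gap and max_jump", {
  set.seed(7)
  t <- cumsum(runif(200, 0.001, 0.02))
  v <- cumsum(rnorm(200, 0, 0.2))
  s <- toy_record(t, v)
  gaps <- c(0.005, 0.01, 0.02, 0.05, Inf)
  jumps <- c(0.1, 0.3, 0.6, Inf)
  verdicts <- outer(gaps, jumps, Vectorize(function(g, j)
    check_continuity(s, max_gap = g, max_jump = j)$continuous))
  # loosening either tolerance never turns a pass into a fail
  for (i in seq_along(gaps)[-1])
    expect_true(all(verdicts[i, ] >= verdicts[i - 1, ]))
  for (j in seq_along(jumps)[-1])
    expect_true(all(verdicts[, j] >= verdicts[, j - 1]))
})

test_that("order preservation is detected and violated correctly", {
  g <- fixture_ecg()
  r <- g$record
  expect_true(is_order_preserved(r, r)$preserved)
  # swap two neighbouring times via opposite-sign noise
  bad <- r
  bad$t[10] <- r$t[11] + 1e-4
  res <- is_order_preserved(r, bad)
  expect_false(res$preserved)
  expect_true(nrow(res$violations) >= 1)
  expect_true(all(res$violations[, "k"] == res$violations[, "i"] + 1))
  # time-bin generalization representatives stay ordered
  gen <- generalize_time(r, generalization_spec(0.1))
  expect_true(all(diff(gen$t) > 0))
  expect_error(is_order_preserved(r, toy_record()), "mismatch")
})
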