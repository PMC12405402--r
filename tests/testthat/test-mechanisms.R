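test_that("bounded perturbation is index-stable, bounded and seeded", {
  g <- fixture_ecg()
  r <- g$record
  # zero scales: identity
  p0 <- perturb_record(r, noise_spec("both"))
  expect_identical(p0$t, r$t)
  expect_identical(p0$v, r$v)
  spec <- noise_spec("both", scale_v = 0.1, scale_t = 0.002,
                     bound_v = 0.25, bound_t = 0.004)
  p1 <- perturb_record(r, spec, seed = 5)
  expect_length(p1$t, length(r$t))
  expect_true(all(abs(p1$t - r$t) <= 0.004))
  expect_true(all(abs(p1$v - r$v) <= 0.25 + 1e-12))
  expect_true(all(p1$v >= r$domain[1] & p1$v <= r$domain[2]))
  expect_identical(perturb_record(r, spec, seed = 5)$v, p1$v)
  expect_false(identical(perturb_record(r, spec, seed = 6)$v, p1$v))
})

test_that("time noise at or below the safe bound never breaks order", {
  g <- fixture_ecg()
  r <- g$record
  b <- order_safe_time_bound(r)
  expect_lt(b, min(diff(r$t)) / 2)
  expect_gt(b, min(diff(r$t)) / 2 * 0.999)
  for (s in 1:100) {
    p <- perturb_record(r, noise_spec("time", scale_t = b, bound_t = b),
                        seed = s)
    expect_true(is_order_preserved(r, p)$preserved)
  }
  # with noise scale at the mean step and loose bounds, order breaks
  mdt <- mean(diff(r$t))
  p <- perturb_record(r, noise_spec("time", scale_t = mdt,
                                    bound_t = 3 * mdt), seed = 1)
  expect_false(is_order_preserved(r, p)$preserved)
})

test_that("truncated Laplace sampling keeps the Laplace scale in-bound", {
  n <- 1e5
  scale <- 0.1
  x <- withr::with_seed(1, tcanon:::rlaplace_trunc(n, scale, Inf))
  # mean absolute deviation of Laplace equals its scale
  expect_lt(abs(mean(abs(x)) - scale), 3 * scale / sqrt(n))
  xb <- withr::with_seed(1, tcanon:::rlaplace_trunc(n, scale, 0.15))
  expect_true(all(abs(xb) <= 0.15))
})

test_that("pointwise DP Laplace perturbs values only and respects epsilon", {
  g <- fixture_ecg()
  r <- g$record
  # huge epsilon: output indistinguishable from input
  d <- dp_pointwise_laplace(r, dp_params(epsilon = 1e6, sensitivity = 1),
                            seed = 2)
  expect_identical(d$t, r$t)
  expect_lt(max(abs(d$v - r$v)), 1e-3)
  # mean absolute noise matches sensitivity/epsilon (pre-clamp)
  flat <- tc_record(seq(0, 99.999, by = 0.001), numeric(1e5),
                    domain = c(-Inf, Inf))
  d2 <- dp_pointwise_laplace(flat, dp_params(epsilon = 2, sensitivity = 1,
                                             clamp = c(-Inf, Inf)),
                             seed = 3)
  expect_lt(abs(mean(abs(d2$v - flat$v)) - 0.5), 3 * 0.5 / sqrt(1e5))
  # continuity survives whenever the input was continuous (same domain)
  d3 <- dp_pointwise_laplace(r, dp_params(epsilon = 50, sensitivity = 0.1),
                             seed = 4)
  expect_true(check_continuity(d3, max_jump = Inf)$continuous)
})

test_that("time generalization bins preserve order and means", {
  g <- fixture_ecg()
  r <- g$record
  gen <- generalize_time(r, generalization_spec(0.2))
  expect_true(all(diff(gen$t) > 0))
  # a constant record generalizes to the same constant
  const <- toy_record(seq(0, 1, by = 0.01), rep(0.7, 101))
  gc <- generalize_time(const, generalization_spec(0.25))
  expect_true(all(gc$v == 0.7))
  # one bin spanning everything gives a single representative
  g1 <- generalize_time(r, generalization_spec(diff(range(r$t)) + 1))
  expect_length(g1$t, 1)
  expect_equal(g1$v, mean(r$v))
  expect_warning(generalize_time(r, generalization_spec(1e-9)), "no-op")
})

test_that("nominal generalization loses continuity by construction", {
  g <- fixture_ecg()
  lab <- generalize_to_label(g$record, gt = g$ground_truth)
  expect_s3_class(lab, "tc_labeled")
  expect_equal(lab$label, "Healthy")
  cc <- check_continuity(lab)
  expect_false(cc$continuous)
  gi <- inject_event(g$record, g$ground_truth, event_spec("st_elevation", 2))
  expect_equal(generalize_to_label(gi$record, gt = gi$ground_truth)$label,
               "MI")
})

test_that("swapping permutes ownership but never touches samples", {
  db <- fixture_db()
  sw <- swap_attribute(db, "ECG", seed = 3)
  expect_setequal(unname(person_map(sw)), unname(person_map(db)))
  for (id in names(db$records)) {
    expect_identical(sw$records[[id]]$t, db$records[[id]]$t)
    expect_identical(sw$records[[id]]$v, db$records[[id]]$v)
    expect_true(check_continuity(sw$records[[id]])$continuous)
  }
  # two records: identity or transposition
  db2 <- tc_database(db$records[1:2])
  sw2 <- swap_attribute(db2, "ECG", seed = 1)
  p0 <- person_map(db2); p1 <- person_map(sw2)
  expect_true(identical(unname(p1), unname(p0)) ||
                identical(unname(p1), unname(rev(p0))))
  expect_error(swap_attribute(db, "SPO2"), "fewer than 2")
})

test_that("redaction suppresses and masks as requested", {
  db <- fixture_db()
  out <- redact(db, "suppress_record", selector = names(db$records)[1])
  expect_length(out$db, length(db) - 1)
  expect_equal(out$report$removed_records, 1L)
  # mask_fraction 0 is the identity
  m0 <- redact(db, "mask", mask_fraction = 0)
  expect_identical(m0$db$records[[1]]$v, db$records[[1]]$v)
  # mask_fraction 1 blanks all values but keeps times
  m1 <- redact(db, "mask", mask_fraction = 1)
  expect_true(all(is.na(m1$db$records[[1]]$v)))
  expect_identical(m1$db$records[[1]]$t, db$records[[1]]$t)
  expect_error(redact(db, "mask", mask_fraction = 1.5), "mask_fraction")
  sup <- redact(db, "suppress_attribute", selector = "ECG")
  expect_length(sup$db, 0)
})
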