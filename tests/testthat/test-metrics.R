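test_that("discrete Frechet distance has metric-like basic behaviour", {
  c1 <- list(t = 0:5, v = c(0, 1, 0, 2, 1, 0))
  expect_equal(discrete_frechet(c1, c1), 0)
  # a pure value offset travels along the diagonal coupling
  c2 <- list(t = 0:5, v = c1$v + 0.7)
  expect_equal(discrete_frechet(c1, c2), 0.7)
  set.seed(42)
  for (i in 1:25) {
    a <- random_polyline(sample(2:6, 1))
    b <- random_polyline(sample(2:6, 1))
    d <- discrete_frechet(a, b)
    expect_gte(d, 0)
    expect_equal(d, discrete_frechet(b, a))
    # never below the Hausdorff distance of the same point sets
    expect_gte(d + 1e-12, baseline_distances(a, b)$hausdorff)
  }
  # standardized variant records its constants
  ds <- discrete_frechet(c1, c2, standardize = TRUE)
  expect_named(attr(ds, "standardization"), c("sd_t", "sd_v"))
})

test_that("baseline distances behave on constructed pairs", {
  c1 <- list(t = seq(0, 1, by = 0.01), v = sin(seq(0, 1, by = 0.01) * 6))
  expect_equal(baseline_distances(c1, c1)$hausdorff, 0)
  expect_equal(baseline_distances(c1, c1)$sted, 0)
  c2 <- list(t = c1$t, v = c1$v + 0.3)
  expect_equal(baseline_distances(c1, c2)$sted, 0.3, tolerance = 1e-12)
  c3 <- list(t = c1$t + 10, v = c1$v)
  expect_error(baseline_distances(c1, c3), "disjoint")
})

test_that("curve norm follows the Fourier definition", {
  zero <- list(t = seq(0, 1, by = 0.01), v = numeric(101))
  expect_equal(curve_norm(zero, norm_params(p = 2, resample_fs = 100)), 0)
  # Parseval: p = 2 norm equals sqrt(n) times the time-domain 2-norm
  g <- fixture_ecg()
  np <- norm_params(p = 2, resample_fs = 500)
  rs <- tcanon:::resample_curve(g$record, 500)
  expect_equal(curve_norm(g$record, np),
               sqrt(length(rs$v)) * sqrt(sum(rs$v^2)),
               tolerance = 1e-9)
  # a cosine at an integer frequency bin: two bins of magnitude a*n/2
  n <- 64; fs <- 64; a <- 0.8
  tt <- (0:(n - 1)) / fs
  cosc <- list(t = tt, v = a * cos(2 * pi * 4 * tt))
  expect_equal(curve_norm(cosc, norm_params(p = 2, resample_fs = fs)),
               a * n / sqrt(2), tolerance = 1e-9)
  expect_error(norm_params(p = 1), "p")
})

test_that("region correction excises only small mismatch regions", {
  t <- seq(0, 2, by = 0.005)
  base <- sin(2 * pi * t)
  x <- list(t = t, v = base)
  y <- list(t = t, v = base)
  cp <- correction_params(tau = 0.1, omega = 0.08)
  # identical curves: nothing corrected
  e0 <- region_correct_E(x, y, cp)
  expect_equal(nrow(e0$regions), 0)
  expect_equal(e0$x$v, e0$y$v)
  # tau = 0 is the identity even under gross mismatch
  y2 <- list(t = t, v = base + 1)
  e1 <- region_correct_E(x, y2, correction_params(tau = 0, omega = 0.08))
  expect_equal(nrow(e1$regions), 0)
  # one short spike is excised and the distance falls back
  xs <- x
  spike <- t >= 1.0 & t <= 1.04
  xs$v[spike] <- xs$v[spike] + 3
  d_before <- discrete_frechet(xs, y)
  e2 <- region_correct_E(xs, y, cp)
  expect_gte(nrow(e2$regions), 1)
  expect_true(any(e2$regions$start <= 1.0 & e2$regions$end >= 1.03))
  expect_lt(discrete_frechet(e2$x, e2$y), 0.1 * d_before)
})

test_that("alignment recovers constructed transforms", {
  g <- fixture_ecg(n_cycles = 2)
  x <- list(t = g$record$t, v = g$record$v)
  # empty family: identity
  a0 <- align_G(x, x, alignment_family(character(0)))
  expect_equal(a0$params$value_offset, 0)
  expect_equal(a0$distance, 0)
  # offset recovery
  xo <- list(t = x$t, v = x$v + 0.2)
  a1 <- align_G(xo, x, alignment_family("value_offset"))
  expect_equal(a1$params$value_offset, -0.2, tolerance = 1e-3)
  expect_lt(a1$distance, 1e-3)
  expect_error(alignment_family("rotate"), "unknown transform")
})

test_that("curve difference is the exact F(G(E(...))) composition", {
  g <- fixture_ecg(n_cycles = 2)
  r <- g$record
  p <- perturb_record(r, noise_spec("value", scale_v = 0.05,
                                    bound_v = 0.15), seed = 3)
  cp <- correction_params(tau = 0.05, omega = 0.1)
  fam <- alignment_family(character(0))
  d <- curve_difference(r, p, cp, fam)
  e <- region_correct_E(r, p, cp)
  gal <- align_G(e$x, e$y, fam)
  expect_identical(as.numeric(d), discrete_frechet(gal$curve, e$y))
  expect_equal(as.numeric(curve_difference(r, r, cp, fam)), 0)
  # with identity available and no correction budget, alignment can only
  # shrink the plain Frechet distance
  cp0 <- correction_params(tau = 0, omega = 0.1)
  fam2 <- alignment_family("value_offset")
  expect_lte(as.numeric(curve_difference(r, p, cp0, fam2)),
             discrete_frechet(r, p) + 1e-9)
  # an offset-only mismatch is absorbed entirely by the family
  ro <- r; ro$v <- r$v + 0.2
  expect_lt(as.numeric(curve_difference(ro, r, cp0, fam2)), 1e-3)
})

test_that("time-continuous MRE follows its normalized definition", {
  g <- fixture_ecg(n_cycles = 2)
  r <- g$record
  np <- norm_params(p = 2, resample_fs = 250)
  cp <- correction_params(tau = 0, omega = 0.1)
  fam <- alignment_family(character(0))
  # identical pairs: N = 0 convention
  m0 <- tc_mre(pair_records(tc_database(list(r)), tc_database(list(r))),
               cp, fam, np)
  expect_equal(as.numeric(m0), 0)
  expect_true(attr(m0, "all_identical"))
  # single pair with d > 0: exactly 1/|c1| regardless of d
  p <- perturb_record(r, noise_spec("value", scale_v = 0.08,
                                    bound_v = 0.2), seed = 2)
  m1 <- tc_mre(pair_records(tc_database(list(r)), tc_database(list(p))),
               cp, fam, np)
  expect_equal(as.numeric(m1), 1 / curve_norm(r, np), tolerance = 1e-9)
  # two pairs with equal d and equal norms: 1/|c|
  r2 <- r; r2$record_id <- "b"
  p2 <- p; p2$record_id <- "b"
  m2 <- tc_mre(pair_records(tc_database(list(r, r2)),
                            tc_database(list(p, p2))), cp, fam, np)
  expect_equal(as.numeric(m2), 1 / curve_norm(r, np), tolerance = 1e-9)
  # zero-norm raw curve is undefined
  z <- tc_record(r$t, numeric(length(r$t)), record_id = r$record_id)
  expect_error(tc_mre(pair_records(tc_database(list(z)),
                                   tc_database(list(p))), cp, fam, np),
               "zero norm")
})

test_that("decision utility counts unchanged decisions", {
  g <- fixture_ecg(n_cycles = 2)
  r <- g$record
  dec <- list(
    positive_mean = function(x) mean(x$v) > 0,
    peak_over_half = function(x) max(x$v) > 0.5,
    long = function(x) length(x$t) > 100)
  expect_equal(as.numeric(decision_utility(dec, r, identity)), 1)
  flip <- function(x) { x$v <- -x$v; x }
  expect_equal(as.numeric(decision_utility(dec[1:2], r, flip)), 0)
  # 2 of 3 decisions unchanged
  damp <- function(x) { x$v <- x$v * 0.4; x }
  expect_equal(as.numeric(decision_utility(dec, r, damp)), 2 / 3)
  expect_error(decision_utility(list(), r, identity), "empty")
})

test_that("width information loss is a fraction of the domain", {
  expect_equal(information_loss_width(rep(0, 100), 10), 0)
  expect_equal(information_loss_width(rep(10, 5), 10), 1)
  expect_equal(information_loss_width(rep(5, 8), 10), 0.5)
  expect_error(information_loss_width(c(1, 2), 0), "domain_width")
  set.seed(1)
  w <- runif(50, 0, 7)
  il <- information_loss_width(w, 7)
  expect_gte(il, 0); expect_lte(il, 1)
})

test_that("edit distance handles standard cases", {
  expect_equal(edit_distance(letters[1:5], letters[1:5]), 0L)
  expect_equal(edit_distance(character(0), letters[1:4]), 4L)
  expect_equal(edit_distance(letters[1:3], character(0)), 3L)
  expect_equal(edit_distance(c("a", "b", "c"), c("a", "x", "c")), 1L)
  # cross-check against the base-R Levenshtein on encoded strings
  set.seed(3)
  for (i in 1:20) {
    a <- sample(letters[1:4], sample(0:8, 1), replace = TRUE)
    b <- sample(letters[1:4], sample(0:8, 1), replace = TRUE)
    expect_equal(edit_distance(a, b),
                 as.integer(utils::adist(paste(a, collapse = ""),
                                         paste(b, collapse = ""))))
  }
})
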