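test_that("generated ECG matches its annotations and stated morphology", {
  g <- fixture_ecg()
  w <- g$ground_truth$waves
  # canonical wave order within each cycle
  for (ci in unique(w$cycle)) {
    wc <- w[w$cycle == ci, ]
    expect_equal(wc$wave, c("P", "PQ", "Q", "R", "S", "ST", "T", "U", "TP"))
    expect_true(all(diff(wc$onset) > 0))
    expect_equal(wc$onset[-1], wc$offset[-nrow(wc)])
  }
  # anchored defaults: P lasts 0.1 s; U is 25% of T in amplitude
  expect_equal(unique(w$duration[w$wave == "P"]), 0.1)
  expect_equal(unique(w$amplitude[w$wave == "U"]) /
                 unique(w$amplitude[w$wave == "T"]), 0.25)
  # signed morphology
  amp <- function(x) unique(w$amplitude[w$wave == x])
  expect_true(amp("P") > 0 && amp("R") > 0 && amp("T") > 0)
  expect_true(amp("Q") < 0 && amp("S") < 0)
  # R peak count equals cycle count
  expect_length(g$ground_truth$r_peaks, g$ground_truth$n_cycles)
  # determinism
  g2 <- generate_ecg(ecg_params(fs = 250), n_cycles = 5, seed = 11)
  expect_identical(g2$record$v, g$record$v)
  g3 <- generate_ecg(ecg_params(fs = 250), n_cycles = 5, seed = 12)
  expect_false(identical(g3$record$v, g$record$v))
  expect_error(generate_ecg(n_cycles = 0), "n_cycles")
})

test_that("every generated record is valid and continuous", {
  db <- fixture_db()
  for (r in db$records) {
    expect_true(all(diff(r$t) > 0))
    expect_true(check_continuity(r, mode = "linear")$continuous)
  }
  for (k in c("spo2", "ibp", "ppg")) {
    r <- generate_aux_channel(k, duration = 20, seed = 3)
    expect_true(check_continuity(r, mode = "linear")$continuous)
  }
})

test_that("event injection modifies only the targeted region", {
  g <- fixture_ecg()
  # ST elevation: flat raise over the stated span, nothing else moves
  gi <- inject_event(g$record, g$ground_truth,
                     event_spec("st_elevation", 3, magnitude = 0.12,
                                width = 0.1))
  st_on <- g$ground_truth$waves$onset[g$ground_truth$waves$cycle == 3 &
                                        g$ground_truth$waves$wave == "ST"]
  inside <- g$record$t >= st_on & g$record$t < st_on + 0.1
  expect_equal(gi$record$v[inside], g$record$v[inside] + 0.12)
  expect_identical(gi$record$v[!inside], g$record$v[!inside])
  expect_equal(gi$ground_truth$events$event_type, "st_elevation")
  # missing U zeroes a single cycle's U wave only
  gm <- inject_event(g$record, g$ground_truth, event_spec("missing_u", 2))
  wu <- gm$ground_truth$waves
  expect_equal(wu$amplitude[wu$wave == "U" & wu$cycle == 2], 0)
  expect_true(all(wu$amplitude[wu$wave == "U" & wu$cycle != 2] > 0))
  # pacemaker spikes sit immediately before each Q onset
  gp <- inject_event(g$record, g$ground_truth, event_spec("pacemaker_spike"))
  q_on <- wu$onset[wu$wave == "Q"]
  ev <- gp$ground_truth$events
  expect_equal(nrow(ev), g$ground_truth$n_cycles)
  expect_equal(ev$time + ev$width, q_on, tolerance = 1e-12)
  expect_error(event_spec("unknown_thing"), "unknown event_type")
  expect_error(inject_event(g$record, g$ground_truth,
                            event_spec("deep_q", 99)), "outside")
})

test_that("database generation gives stable per-person profiles", {
  db <- fixture_db()
  expect_length(db, 10)
  pm <- person_map(db)
  expect_equal(unname(table(pm)), rep(2L, 5), ignore_attr = TRUE)
  gt <- attr(db, "ground_truth")
  expect_equal(nrow(gt$profiles), 5)
  # same person's two records share heart rate to within the tiny drift
  for (p in gt$profiles$person_id) {
    ids <- names(pm)[pm == p]
    rr <- vapply(ids, function(id)
      mean(diff(gt$record_gt[[id]]$r_peaks)), numeric(1))
    expect_lt(abs(diff(rr)) / mean(rr), 0.05)
  }
  # changing the seed redraws rates but keeps the structure
  db2 <- generate_database(n_persons = 5, records_per_person = 2,
                           seed = 43, distinct_rr = FALSE)
  expect_length(db2, 10)
  expect_false(identical(attr(db2, "ground_truth")$profiles$heart_rate,
                         gt$profiles$heart_rate))
})

test_that("auxiliary channels respect their units and sampling character", {
  spo2 <- generate_aux_channel("spo2", duration = 60, seed = 2)
  expect_true(all(spo2$v >= 0 & spo2$v <= 100))
  expect_equal(spo2$unit, "%")
  nibp <- generate_aux_channel("nibp", duration = 120, seed = 2)
  ibp <- generate_aux_channel("ibp", duration = 120, seed = 2)
  expect_lt(length(nibp$t), 10)          # sparse, a few readings
  expect_gt(length(ibp$t), 1000)         # dense waveform
  expect_equal(nibp$unit, "mmHg")
  # ppg and ibp with the same seed stay phase-locked within one beat
  pp <- generate_aux_channel("ppg", 30, seed = 5, heart_rate = 60)
  ib <- generate_aux_channel("ibp", 30, seed = 5, heart_rate = 60)
  ppk <- pp$t[which(diff(sign(diff(pp$v))) < 0) + 1]
  ipk <- ib$t[which(diff(sign(diff(ib$v))) < 0) + 1]
  n <- min(length(ppk), length(ipk))
  expect_true(all(abs(ppk[1:n] - ipk[1:n]) < 1))
  expect_error(generate_aux_channel("eeg"), "arg")
})
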