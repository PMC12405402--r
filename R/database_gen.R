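#' Generate a multi-person ECG database with linkage ground truth
#'
#' Builds `n_persons * records_per_person` ECG records. Each person has a
#' stable resting heart rate (hence a stable RR interval), a stable U-wave
#' presence flag, and a stable event signature (a small set of diagnostic
#' events injected at fixed cycles) shared across their records; only the
#' beat-to-beat jitter and a tiny per-record rate drift differ between the
#' records of one person. This is the fixture source for the linkage
#' attacks: with `distinct_rr = TRUE`, person heart rates are spread evenly
#' across `hr_range` so per-person RR intervals are disjoint and inter-beat
#' timing alone identifies every person.
#'
#' @param n_persons,records_per_person counts (>= 1).
#' @param seed RNG seed; all randomness derives from it.
#' @param hr_range heart-rate range in bpm over which persons are spread.
#' @param hr_values optional explicit per-person heart rates (overrides
#'   `hr_range`).
#' @param distinct_rr if `TRUE` (default), person rates are evenly spaced;
#'   if `FALSE`, drawn uniformly (possibly overlapping).
#' @param n_cycles cycles per record.
#' @param fs sampling frequency in Hz.
#' @param u_prob probability that a person has a U wave.
#' @param max_events maximum number of signature events per person
#'   (uniform on `0:max_events`).
#' @param rr_jitter per-record beat-to-beat jitter fraction.
#' @return a `tc_database`; `attr(db, "ground_truth")` holds `profiles`
#'   (per-person heart rate, U-wave flag, signature events) and
#'   `record_gt`, the per-record `ecg_ground_truth` objects.
#' @export
generate_database <- function(n_persons = 5, records_per_person = 2,
                              seed = 1L, hr_range = c(55, 95),
                              hr_values = NULL, distinct_rr = TRUE,
                              n_cycles = 8, fs = 250, u_prob = 0.5,
                              max_events = 2, rr_jitter = 0.02) {
  stopifnot(n_persons >= 1, records_per_person >= 1)
  ev_pool <- c("deep_q", "shallow_s", "shallow_r", "missing_u",
               "pacemaker_spike", "st_elevation")
  prof <- withr::with_seed(seed, {
    hr <- if (!is.null(hr_values)) {
      stopifnot(length(hr_values) == n_persons)
      hr_values
    } else if (distinct_rr && n_persons > 1) {
      seq(hr_range[1], hr_range[2], length.out = n_persons)
    } else if (distinct_rr) {
      mean(hr_range)
    } else {
      stats::runif(n_persons, hr_range[1], hr_range[2])
    }
    u <- stats::runif(n_persons) < u_prob
    sig <- lapply(seq_len(n_persons), function(i) {
      k <- sample(0:max_events, 1)
      if (k == 0) return(list())
      types <- sample(ev_pool, k, replace = FALSE)
      cycles <- sample(seq(2, max(2, n_cycles - 1)), k, replace = TRUE)
      Map(function(ty, cy) event_spec(ty, cycle_index = cy), types, cycles)
    })
    list(hr = hr, u = u, sig = sig)
  })

  records <- list()
  record_gt <- list()
  k <- 0L
  for (p in seq_len(n_persons)) {
    for (r in seq_len(records_per_person)) {
      k <- k + 1L
      s <- derive_seed(seed, 1000L + k)
      hr_r <- withr::with_seed(s, prof$hr[p] * (1 + 0.002 * stats::rnorm(1)))
      params <- ecg_params(fs = fs, heart_rate = hr_r,
                           u_present = prof$u[p], rr_jitter = rr_jitter)
      rid <- sprintf("p%02d_r%02d", p, r)
      g <- generate_ecg(params, n_cycles = n_cycles,
                        seed = derive_seed(s, 2L),
                        record_id = rid, person_id = sprintf("p%02d", p))
      for (spec in prof$sig[[p]]) {
        g2 <- inject_event(g$record, g$ground_truth, spec)
        g <- list(record = g2$record, ground_truth = g2$ground_truth)
      }
      records[[rid]] <- g$record
      record_gt[[rid]] <- g$ground_truth
    }
  }
  db <- tc_database(records)
  attr(db, "ground_truth") <- list(
    profiles = data.frame(person_id = sprintf("p%02d", seq_len(n_persons)),
                          heart_rate = prof$hr, u_present = prof$u),
    signatures = prof$sig, record_gt = record_gt)
  db
}
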