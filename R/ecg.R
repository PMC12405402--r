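#' Synthetic ECG generator parameters
#'
#' Parameters of the morphological single-lead ECG template. Each cardiac
#' cycle is laid out as P wave, PQ segment, QRS complex (Q, R, S), ST
#' segment, T wave, optional U wave, and a TP filler interval; the PQ
#' segment is the zero baseline reference. Waves are signed raised-cosine
#' lobes (P+, Q-, R+, S-, T+, U+) with closed-form onsets and offsets.
#' The physiologically anchored defaults are the P-wave duration of 0.1 s
#' and a U wave at 25% of the T-wave amplitude; the remaining amplitudes
#' and durations are package defaults in the usual clinical ranges.
#'
#' @param fs sampling frequency in Hz (>= 100).
#' @param heart_rate heart rate in bpm.
#' @param p_amp,q_amp,r_amp,s_amp,t_amp wave peak amplitudes in mV.
#' @param p_dur,q_dur,r_dur,s_dur,t_dur,u_dur wave durations in seconds.
#' @param pq_segment,st_segment baseline segment durations in seconds.
#' @param u_present logical: include a U wave.
#' @param u_amp_ratio U peak amplitude as a fraction of the T amplitude.
#' @param rr_jitter relative sd of the multiplicative Gaussian jitter on the
#'   TP interval (wave durations stay fixed so annotations remain exact).
#' @param seed default RNG seed for [generate_ecg()].
#' @return list of class `ecg_params`.
#' @export
ecg_params <- function(fs = 500, heart_rate = 60,
                       p_amp = 0.15, q_amp = -0.10, r_amp = 1.00,
                       s_amp = -0.15, t_amp = 0.30,
                       p_dur = 0.10, q_dur = 0.03, r_dur = 0.05,
                       s_dur = 0.03, t_dur = 0.16, u_dur = 0.08,
                       pq_segment = 0.06, st_segment = 0.10,
                       u_present = TRUE, u_amp_ratio = 0.25,
                       rr_jitter = 0.02, seed = 1L) {
  stopifnot(fs >= 100, heart_rate > 0,
            p_dur > 0, q_dur > 0, r_dur > 0, s_dur > 0, t_dur > 0,
            u_dur > 0, pq_segment > 0, st_segment > 0,
            u_amp_ratio >= 0, rr_jitter >= 0)
  rr <- 60 / heart_rate
  busy <- p_dur + pq_segment + q_dur + r_dur + s_dur + st_segment +
    t_dur + u_dur
  if (busy >= rr)
    stop("wave durations exceed the cardiac cycle at ", heart_rate, " bpm",
         call. = FALSE)
  structure(as.list(environment()), class = "ecg_params")
}

# raised-cosine lobe of amplitude `amp` supported on [onset, onset + dur]
.lobe <- function(t, onset, dur, amp) {
  w <- t >= onset & t <= onset + dur
  out <- numeric(length(t))
  out[w] <- amp * 0.5 * (1 - cos(2 * pi * (t[w] - onset) / dur))
  out
}

#' Generate an annotated synthetic ECG record
#'
#' Builds `n_cycles` cardiac cycles from the template in `params` on an
#' equidistant grid. Per-cycle beat-to-beat variability comes only from
#' multiplicative Gaussian jitter on the TP interval, so all annotated wave
#' onsets, offsets and amplitudes are exact by construction. The generator
#' is deterministic for a fixed seed.
#'
#' @param params an [ecg_params()] object.
#' @param n_cycles number of cardiac cycles (>= 1).
#' @param seed RNG seed; defaults to `params$seed`.
#' @param record_id,person_id identifiers stored on the record.
#' @return list with `record` (a `tc_record`) and `ground_truth`, a list of
#'   class `ecg_ground_truth` holding `waves` (per-cycle onset/offset/
#'   amplitude table), `r_peaks`, `rr` (per-cycle lengths), `events`
#'   (injected events, initially empty) and the generating parameters.
#' @export
generate_ecg <- function(params = ecg_params(), n_cycles = 10,
                         seed = params$seed,
                         record_id = "ecg1", person_id = NA_character_) {
  stopifnot(inherits(params, "ecg_params"))
  if (n_cycles < 1) stop("n_cycles must be >= 1", call. = FALSE)
  p <- params
  rr0 <- 60 / p$heart_rate
  busy <- p$p_dur + p$pq_segment + p$q_dur + p$r_dur + p$s_dur +
    p$st_segment + p$t_dur + p$u_dur
  tp0 <- rr0 - busy
  tp <- withr::with_seed(seed, {
    pmax(0.2 * tp0, tp0 * (1 + p$rr_jitter * stats::rnorm(n_cycles)))
  })
  cyc_len <- busy + tp
  cyc_on <- c(0, cumsum(cyc_len))[seq_len(n_cycles)]

  u_amp <- if (p$u_present) p$u_amp_ratio * p$t_amp else 0
  wave_names <- c("P", "PQ", "Q", "R", "S", "ST", "T", "U", "TP")
  durs <- c(p$p_dur, p$pq_segment, p$q_dur, p$r_dur, p$s_dur,
            p$st_segment, p$t_dur, p$u_dur, NA)
  amps <- c(p$p_amp, 0, p$q_amp, p$r_amp, p$s_amp, 0, p$t_amp, u_amp, 0)

  waves <- do.call(rbind, lapply(seq_len(n_cycles), function(ci) {
    d <- durs; d[9] <- tp[ci]
    on <- cyc_on[ci] + c(0, cumsum(d))[seq_along(d)]
    data.frame(cycle = ci, wave = wave_names, onset = on, offset = on + d,
               duration = d, amplitude = amps)
  }))
  rownames(waves) <- NULL

  t_total <- sum(cyc_len)
  tt <- seq(0, t_total, by = 1 / p$fs)
  vv <- numeric(length(tt))
  lobed <- waves[waves$amplitude != 0, ]
  for (i in seq_len(nrow(lobed)))
    vv <- vv + .lobe(tt, lobed$onset[i], lobed$duration[i],
                     lobed$amplitude[i])

  rec <- tc_record(tt, vv, channel = "ECG", unit = "mV",
                   domain = channel_defaults("ECG")$domain,
                   fs_nominal = p$fs, record_id = record_id,
                   person_id = person_id)
  r_rows <- waves[waves$wave == "R", ]
  gt <- structure(
    list(waves = waves,
         r_peaks = r_rows$onset + r_rows$duration / 2,
         rr = cyc_len, n_cycles = n_cycles, params = p,
         events = data.frame(event_type = character(0), cycle = integer(0),
                             time = numeric(0), magnitude = numeric(0),
                             width = numeric(0))),
    class = "ecg_ground_truth")
  list(record = rec, ground_truth = gt)
}

#' Specify a diagnostic event to inject
#'
#' The event alphabet mirrors the identifiable ECG features used by the
#' linkage attacks: an abnormally deep Q wave (possible Q-wave infarction),
#' a particularly shallow S wave, a missing U wave in a single cycle, a
#' shallow R wave (possible prior infarction), a narrow pacemaker
#' stimulation spike immediately before the Q wave, and a sustained ST
#' elevation (the infarction-indicative feature).
#'
#' @param event_type one of `"deep_q"`, `"shallow_s"`, `"missing_u"`,
#'   `"shallow_r"`, `"pacemaker_spike"`, `"st_elevation"`.
#' @param cycle_index 1-based cycle to modify, or `NULL` for every cycle.
#' @param magnitude event magnitude: the new wave peak amplitude in mV for
#'   the wave-shape events, the spike amplitude for `pacemaker_spike`, or
#'   the elevation in mV for `st_elevation`. `NULL` picks the default.
#' @param width event width in seconds (`pacemaker_spike` default 0.008,
#'   `st_elevation` default 0.1); ignored otherwise.
#' @return list of class `event_spec`.
#' @export
event_spec <- function(event_type, cycle_index = NULL, magnitude = NULL,
                       width = NULL) {
  types <- c("deep_q", "shallow_s", "missing_u", "shallow_r",
             "pacemaker_spike", "st_elevation")
  if (!event_type %in% types)
    stop("unknown event_type: ", event_type, call. = FALSE)
  defaults <- list(deep_q = c(-0.35, NA), shallow_s = c(-0.03, NA),
                   missing_u = c(0, NA), shallow_r = c(0.40, NA),
                   pacemaker_spike = c(0.30, 0.008),
                   st_elevation = c(0.12, 0.100))
  d <- defaults[[event_type]]
  structure(list(event_type = event_type, cycle_index = cycle_index,
                 magnitude = if (is.null(magnitude)) d[1] else magnitude,
                 width = if (is.null(width)) d[2] else width),
            class = "event_spec")
}

#' Inject a diagnostic event into a generated ECG
#'
#' Locally modifies the waveform of the targeted cycle(s) and appends the
#' event to the ground truth; samples outside the event are untouched.
#' Wave-amplitude events replace the annotated raised-cosine lobe with one
#' of the requested amplitude; `pacemaker_spike` adds a narrow lobe ending
#' at the Q-wave onset; `st_elevation` raises all samples in
#' `[ST onset, ST onset + width)` by `magnitude` (a rectangular elevation
#' starting at the J point, possibly extending into the T wave).
#'
#' @param rec the `tc_record` from [generate_ecg()].
#' @param gt its `ecg_ground_truth`.
#' @param spec an [event_spec()].
#' @return list with modified `record` and `ground_truth`.
#' @export
inject_event <- function(rec, gt, spec) {
  stopifnot(inherits(rec, "tc_record"), inherits(gt, "ecg_ground_truth"),
            inherits(spec, "event_spec"))
  cycles <- if (is.null(spec$cycle_index)) seq_len(gt$n_cycles) else
    spec$cycle_index
  if (any(cycles < 1 | cycles > gt$n_cycles))
    stop("cycle_index outside the generated cycles", call. = FALSE)

  wave_of <- c(deep_q = "Q", shallow_s = "S", shallow_r = "R",
               missing_u = "U")
  for (ci in cycles) {
    if (spec$event_type %in% names(wave_of)) {
      wn <- wave_of[[spec$event_type]]
      row <- which(gt$waves$cycle == ci & gt$waves$wave == wn)
      w <- gt$waves[row, ]
      old <- .lobe(rec$t, w$onset, w$duration, w$amplitude)
      new <- .lobe(rec$t, w$onset, w$duration, spec$magnitude)
      rec$v <- rec$v - old + new
      gt$waves$amplitude[row] <- spec$magnitude
      ev_time <- w$onset
    } else if (spec$event_type == "pacemaker_spike") {
      q_on <- gt$waves$onset[gt$waves$cycle == ci & gt$waves$wave == "Q"]
      on <- q_on - spec$width
      rec$v <- rec$v + .lobe(rec$t, on, spec$width, spec$magnitude)
      ev_time <- on
    } else { # st_elevation
      st_on <- gt$waves$onset[gt$waves$cycle == ci & gt$waves$wave == "ST"]
      w <- rec$t >= st_on & rec$t < st_on + spec$width
      rec$v[w] <- rec$v[w] + spec$magnitude
      ev_time <- st_on
    }
    gt$events <- rbind(gt$events, data.frame(
      event_type = spec$event_type, cycle = ci, time = ev_time,
      magnitude = spec$magnitude, width = spec$width))
  }
  gt$events <- gt$events[order(gt$events$time), ]
  rownames(gt$events) <- NULL
  list(record = rec, ground_truth = gt)
}
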