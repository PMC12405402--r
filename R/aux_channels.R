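#' Generate an auxiliary patient-monitor channel
#'
#' Piecewise-smooth synthetic vitals in the conventional patient-monitor
#' units: heart frequency (HF) and peripheral pulse in bpm, peripheral
#' oxygen saturation (SPO2) in %, breathing frequency (BF) in 1/min,
#' non-invasive and invasive blood pressure (NIBP/IBP) in mmHg, and a
#' normalized photoplethysmogram (PPG). NIBP is sparse (a few readings per
#' hour, scaled to the requested duration) while IBP is a dense pressure
#' waveform. PPG and IBP derive their beat onsets from the same
#' seed-derived cardiac cycle, so with an identical seed their pulse peaks
#' stay phase-locked within one cardiac period.
#'
#' @param kind one of `"spo2"`, `"hf"`, `"pulse"`, `"bf"`, `"nibp"`,
#'   `"ibp"`, `"ppg"`.
#' @param duration length of the record in seconds.
#' @param seed RNG seed.
#' @param heart_rate cardiac rate in bpm used by `"ibp"` and `"ppg"`.
#' @param record_id,person_id identifiers stored on the record.
#' @return a `tc_record` in the channel's unit.
#' @export
generate_aux_channel <- function(kind = c("spo2", "hf", "pulse", "bf",
                                          "nibp", "ibp", "ppg"),
                                 duration = 60, seed = 1L, heart_rate = 60,
                                 record_id = paste0(kind, "1"),
                                 person_id = NA_character_) {
  kind <- match.arg(kind)
  stopifnot(duration > 0)
  # beat onsets shared by the pressure/ppg pair for a given seed
  beats <- withr::with_seed(derive_seed(seed, 99L), {
    rr <- 60 / heart_rate
    n <- ceiling(duration / (0.9 * rr)) + 2L
    on <- cumsum(c(0, rr * (1 + 0.03 * stats::rnorm(n))))
    on[on <= duration]
  })
  slow <- function(t, base, amp1, per1, amp2, per2, noise_sd) {
    ph <- stats::runif(2, 0, 2 * pi)
    base + amp1 * sin(2 * pi * t / per1 + ph[1]) +
      amp2 * sin(2 * pi * t / per2 + ph[2]) +
      stats::filter(stats::rnorm(length(t), 0, noise_sd), 0.9,
                    method = "recursive")
  }
  pulse_shape <- function(t, onsets, rr) {
    # sharp systolic upstroke, slower diastolic decay
    v <- numeric(length(t))
    for (on in onsets) {
      ph <- (t - on) / rr
      w <- ph >= 0 & ph < 1
      v[w] <- pmax(v[w], (ph[w] / 0.15)^2 * exp(2 * (1 - ph[w] / 0.15)))
    }
    v # peaks at 1, at phase 0.15 of each beat
  }
  withr::with_seed(seed, {
    rr <- 60 / heart_rate
    ch <- switch(kind,
      spo2 = {
        tt <- seq(0, duration, by = 1)
        vv <- pmin(100, pmax(0, slow(tt, 97, 0.8, 45, 0.4, 13, 0.15)))
        list(tt, vv, "SPO2")
      },
      hf = {
        tt <- seq(0, duration, by = 1)
        list(tt, pmax(20, slow(tt, heart_rate, 2, 60, 1, 17, 0.3)), "HF")
      },
      pulse = {
        tt <- seq(0, duration, by = 1)
        list(tt, pmax(20, slow(tt, heart_rate, 2, 60, 1, 19, 0.3)), "Pulse")
      },
      bf = {
        tt <- seq(0, duration, by = 1)
        list(tt, pmax(4, slow(tt, 15, 1.5, 90, 0.5, 21, 0.2)), "BF")
      },
      nibp = {
        # a few readings per hour, scaled down to the requested duration
        n <- max(2L, round(duration / 30))
        tt <- sort(stats::runif(n, 0, duration))
        list(tt, 120 + 6 * stats::rnorm(n), "NIBP")
      },
      ibp = {
        tt <- seq(0, duration, by = 1 / 100)
        vv <- 75 + 45 * pulse_shape(tt, beats, rr)
        list(tt, vv, "IBP")
      },
      ppg = {
        tt <- seq(0, duration, by = 1 / 100)
        vv <- pulse_shape(tt, beats + 0.12, rr) # pulse-transit delay
        list(tt, pmin(1, pmax(0, vv)), "PPG")
      })
    cd <- channel_defaults(ch[[3]])
    tc_record(ch[[1]], ch[[2]], channel = ch[[3]], unit = cd$unit,
              domain = cd$domain,
              fs_nominal = 1 / stats::median(diff(ch[[1]])),
              record_id = record_id, person_id = person_id)
  })
}
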