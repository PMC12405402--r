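#' Event-detector configuration
#'
#' Thresholds of the rule-based ECG event detector. The myocardial
#' infarction (ST elevation) criterion defaults to the clinical rule of an
#' elevation of at least 0.1 mV sustained for at least 80 ms. The
#' wave-shape thresholds are relative to the per-record R amplitude and
#' are package defaults (the events themselves, not their thresholds, are
#' the clinically defined quantities): a Q wave deeper than 0.25 of the
#' cycle's R amplitude, an S wave shallower than half the Q depth, an R
#' wave below half the record's median R amplitude, a pacemaker spike
#' above 0.2 mV in the PQ window, and a U wave counted present above
#' 0.03 mV.
#'
#' @param r_peak_frac R peaks are local maxima above this fraction of the
#'   record maximum.
#' @param refractory minimum R-to-R spacing in seconds.
#' @param st_elev_min minimum infarction-indicative ST elevation in mV.
#' @param st_width_min minimum sustained elevation width in seconds.
#' @param deep_q_frac deep-Q threshold as a fraction of R amplitude.
#' @param shallow_s_frac shallow-S threshold as a fraction of Q depth.
#' @param shallow_r_frac shallow-R threshold as a fraction of the record's
#'   median R amplitude.
#' @param pacer_min_amp,pacer_max_width pacemaker-spike amplitude (mV) and
#'   width (s) limits.
#' @param u_min_amp minimum amplitude (mV) for a U wave to count as
#'   present.
#' @param windows named list of per-cycle search windows in seconds
#'   relative to the R peak (each `c(from, to)`).
#' @return list of class `detector_config`.
#' @export
detector_config <- function(r_peak_frac = 0.3, refractory = 0.3,
                            st_elev_min = 0.1, st_width_min = 0.080,
                            deep_q_frac = 0.25, shallow_s_frac = 0.5,
                            shallow_r_frac = 0.5,
                            pacer_min_amp = 0.2, pacer_max_width = 0.020,
                            u_min_amp = 0.03,
                            windows = list(q = c(-0.080, -0.005),
                                           s = c(0.005, 0.080),
                                           pacer = c(-0.110, -0.050),
                                           t = c(0.150, 0.320),
                                           u = c(0.320, 0.440))) {
  structure(as.list(environment()), class = "detector_config")
}

.win_stat <- function(t, v, center, win, fun) {
  w <- which(t >= center + win[1] & t <= center + win[2])
  if (!length(w)) return(c(NA_real_, NA_real_))
  i <- w[fun(v[w])]
  c(v[i], t[i])
}

#' Detect diagnostic events in an ECG record
#'
#' A rule-based detector: R peaks are local maxima above a fraction of the
#' record maximum separated by a refractory window; every other feature is
#' searched in fixed windows relative to each detected R peak. Emitted
#' event types: `r_peak`, `deep_q`, `shallow_s`, `shallow_r`, `missing_u`
#' (a cycle without U wave while most other cycles have one),
#' `pacemaker_spike` (a narrow high spike in the PQ window) and
#' `st_elevation` (baseline elevation of at least `st_elev_min` sustained
#' for at least `st_width_min`, measured as the contiguous elevated run
#' starting at the J point).
#'
#' @param rec an ECG `tc_record`.
#' @param config a [detector_config()].
#' @return data frame of events (`event_type`, `time`, `cycle`,
#'   `magnitude`), ordered by time; attribute `"u_present"` flags whether
#'   the record as a whole exhibits a U wave.
#' @export
detect_events <- function(rec, config = detector_config()) {
  stopifnot(inherits(rec, "tc_sample_seq"))
  t <- rec$t; v <- rec$v
  if (diff(range(t)) < 0.4)
    stop("record too short for a single cardiac cycle", call. = FALSE)
  v0 <- ifelse(is.na(v), 0, v)
  thr <- config$r_peak_frac * max(v0)
  loc <- which(diff(sign(diff(v0))) < 0) + 1L # local maxima
  loc <- loc[v0[loc] >= thr]
  r_idx <- integer(0)
  for (i in loc) { # refractory pruning, keep the larger peak
    if (!length(r_idx) || t[i] - t[r_idx[length(r_idx)]] > config$refractory)
      r_idx <- c(r_idx, i)
    else if (v0[i] > v0[r_idx[length(r_idx)]]) r_idx[length(r_idx)] <- i
  }
  if (!length(r_idx))
    stop("no R peaks detected", call. = FALSE)
  r_t <- t[r_idx]; r_v <- v0[r_idx]
  n_cyc <- length(r_idx)
  med_r <- stats::median(r_v)
  dt <- stats::median(diff(t))

  ev <- list(data.frame(event_type = "r_peak", time = r_t,
                        cycle = seq_len(n_cyc), magnitude = r_v))
  u_amp <- numeric(n_cyc)
  for (ci in seq_len(n_cyc)) {
    rc <- r_t[ci]
    up_lim <- if (ci < n_cyc) r_t[ci + 1] - 0.25 else Inf
    q <- .win_stat(t, v0, rc, config$windows$q, which.min)
    s <- .win_stat(t, v0, rc, config$windows$s, which.min)
    pc <- .win_stat(t, v0, rc, config$windows$pacer, which.max)
    uw <- config$windows$u
    uw[2] <- min(uw[2], up_lim - rc)
    u <- if (uw[2] > uw[1]) .win_stat(t, v0, rc, uw, which.max)
         else c(0, NA_real_)
    u_amp[ci] <- max(0, u[1], na.rm = TRUE)

    if (!is.na(q[1]) && abs(q[1]) > config$deep_q_frac * r_v[ci] &&
        q[1] < 0)
      ev[[length(ev) + 1L]] <- data.frame(event_type = "deep_q",
                                          time = q[2], cycle = ci,
                                          magnitude = q[1])
    if (!is.na(s[1]) && !is.na(q[1]) && q[1] < 0 &&
        abs(s[1]) < config$shallow_s_frac * abs(q[1]))
      ev[[length(ev) + 1L]] <- data.frame(event_type = "shallow_s",
                                          time = s[2], cycle = ci,
                                          magnitude = s[1])
    if (r_v[ci] < config$shallow_r_frac * med_r)
      ev[[length(ev) + 1L]] <- data.frame(event_type = "shallow_r",
                                          time = rc, cycle = ci,
                                          magnitude = r_v[ci])
    if (!is.na(pc[1]) && pc[1] > config$pacer_min_amp) {
      # narrowness: width above half the spike maximum
      w <- which(t >= rc + config$windows$pacer[1] &
                   t <= rc + config$windows$pacer[2])
      width <- sum(v0[w] > pc[1] / 2) * dt
      if (width <= config$pacer_max_width)
        ev[[length(ev) + 1L]] <- data.frame(event_type = "pacemaker_spike",
                                            time = pc[2], cycle = ci,
                                            magnitude = pc[1])
    }
    st <- .st_elevation(t, v0, rc, config, dt)
    if (!is.null(st))
      ev[[length(ev) + 1L]] <- data.frame(event_type = "st_elevation",
                                          time = st[2], cycle = ci,
                                          magnitude = st[1])
  }
  # missing U: a cycle without U while the record otherwise has one
  have_u <- u_amp >= config$u_min_amp
  u_present <- mean(have_u) > 0.5
  if (u_present && any(!have_u)) {
    for (ci in which(!have_u))
      ev[[length(ev) + 1L]] <- data.frame(event_type = "missing_u",
                                          time = r_t[ci] +
                                            config$windows$u[1],
                                          cycle = ci,
                                          magnitude = u_amp[ci])
  }
  out <- do.call(rbind, ev)
  out <- out[order(out$time), ]
  rownames(out) <- NULL
  attr(out, "u_present") <- u_present
  out
}

# ST-elevation measurement for one cycle: locate the J point (first sample
# after the S trough where the recovery slope flattens and the value is
# near or above baseline), then measure the contiguous run of samples at
# or above the elevation threshold starting within 10 ms of J.
.st_elevation <- function(t, v, rc, config, dt) {
  sw <- which(t >= rc + config$windows$s[1] & t <= rc + config$windows$s[2])
  if (!length(sw)) return(NULL)
  s_idx <- sw[which.min(v[sw])]
  n <- length(v)
  j <- NA_integer_
  i <- s_idx
  slope_eps <- 0.005
  while (i < n - 1L && t[i] < rc + 0.25) {
    if (v[i] > -0.05 && (v[i + 1L] - v[i]) < slope_eps) { j <- i; break }
    i <- i + 1L
  }
  if (is.na(j)) return(NULL)
  look <- j:min(n, j + ceiling(0.010 / dt))
  elev <- config$st_elev_min - 1e-9
  k0 <- look[which(v[look] >= elev)[1]]
  if (is.na(k0)) return(NULL)
  k1 <- k0
  while (k1 < n && v[k1 + 1L] >= elev) k1 <- k1 + 1L
  run <- (k1 - k0 + 1L) * dt
  if (run >= config$st_width_min - 1e-9)
    c(stats::median(v[k0:k1]), t[k0])
  else NULL
}
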