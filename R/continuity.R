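#' Classify the step time of a sample sequence
#'
#' Decides whether a sampled signal has equidistant time steps or a variable
#' step size. The sequence is equidistant when every inter-sample interval
#' agrees with the first one up to a relative tolerance:
#' `max |dt_i - dt_1| <= rel_tol * dt_1`.
#'
#' @param seq a `tc_sample_seq` (or `tc_record`) with at least 2 samples and
#'   strictly increasing times.
#' @param rel_tol relative tolerance on the step agreement; defaults to
#'   `1e-6` which treats floating-point grids as exact.
#' @return a list of class `step_time_report` with `classification`
#'   (`"equidistant"` or `"variable"`), `delta_ts`, `mean_dt`, `min_dt`.
#' @export
classify_step_time <- function(seq, rel_tol = 1e-6) {
  stopifnot(inherits(seq, "tc_sample_seq"))
  if (length(seq$t) < 2)
    stop("step-time classification needs at least 2 samples", call. = FALSE)
  if (any(diff(seq$t) <= 0))
    stop("times must be strictly increasing", call. = FALSE)
  dts <- diff(seq$t)
  eq <- max(abs(dts - dts[1])) <= rel_tol * dts[1]
  structure(
    list(classification = if (eq) "equidistant" else "variable",
         delta_ts = dts, mean_dt = mean(dts), min_dt = min(dts)),
    class = "step_time_report")
}

#' @export
print.step_time_report <- function(x, ...) {
  cat(sprintf("<step_time_report> %s; mean dt %.6g s, min dt %.6g s, %d steps\n",
              x$classification, x$mean_dt, x$min_dt, length(x$delta_ts)))
  invisible(x)
}

#' Interpolate a record at arbitrary time points
#'
#' Two interpolates are provided. `"hold"` carries the last stored value
#' forward; it is defined for all `t >= t_0` but introduces jumps at every
#' sample, so a record whose gaps require it cannot be continuous.
#' `"linear"` evaluates the chord between the two bracketing samples and is
#' defined on `[t_0, t_n]`; at a stored time it returns the stored value
#' exactly. Outside the mode's domain of definition an undefined-point
#' error is raised.
#'
#' @param rec a `tc_record`.
#' @param t numeric vector of query times (seconds).
#' @param mode `"linear"` (default) or `"hold"`.
#' @return numeric vector of interpolated values.
#' @export
tc_interpolate <- function(rec, t, mode = c("linear", "hold")) {
  mode <- match.arg(mode)
  stopifnot(inherits(rec, "tc_sample_seq"), is.numeric(t))
  if (any(diff(rec$t) <= 0))
    stop("record times must be strictly increasing", call. = FALSE)
  t0 <- rec$t[1]; tn <- rec$t[length(rec$t)]
  if (mode == "hold") {
    if (any(t < t0))
      stop("undefined point: hold interpolate is undefined before the ",
           "first sample", call. = FALSE)
    out <- stats::approx(rec$t, rec$v, xout = t, method = "constant",
                         f = 0, rule = 2)$y
  } else {
    if (any(t < t0 | t > tn))
      stop("undefined point: linear interpolate is only defined between ",
           "the first and last sample", call. = FALSE)
    out <- stats::approx(rec$t, rec$v, xout = t, method = "linear",
                         rule = 1)$y
  }
  # exactness at stored sample times, immune to interpolation round-off
  hit <- match(t, rec$t)
  out[!is.na(hit)] <- rec$v[hit[!is.na(hit)]]
  out
}

#' Check practical continuity of a sample sequence
#'
#' A sampled record is treated as continuous when a jump-free interpolation
#' of it exists. That is operationalized as three testable conditions:
#' the sampling rate is high enough (no inter-sample gap exceeds
#' `max_gap`), an interpolate can be defined between every pair of samples
#' (`interpolable`), and the interpolate introduces no jumps (`no_jumps`:
#' no duplicate time carries differing values, and no per-step value change
#' exceeds `max_jump`). The hold interpolate produces a jump at every value
#' change, so under `mode = "hold"` any non-constant sequence fails
#' `no_jumps`.
#'
#' @param seq a `tc_sample_seq`; duplicate timestamps are permitted here
#'   (they are what the check is for), non-monotone times are not.
#' @param mode interpolate used between samples, `"linear"` or `"hold"`.
#' @param max_gap largest admissible inter-sample gap in seconds; default
#'   3x the median step.
#' @param max_jump largest admissible per-step value change in channel
#'   units; default from [channel_defaults()] for the sequence's channel.
#' @param ... passed to methods.
#' @return a list of class `continuity_report` with `continuous`,
#'   `failed_conditions` (subset of `c("sampling_rate", "interpolable",
#'   "no_jumps")`) and a `violations` data frame (`index`, `time`, `kind`).
#' @export
check_continuity <- function(seq, ...) UseMethod("check_continuity")

#' @rdname check_continuity
#' @export
check_continuity.tc_sample_seq <- function(seq, mode = c("linear", "hold"),
                                           max_gap = NULL, max_jump = NULL,
                                           ...) {
  mode <- match.arg(mode)
  if (length(seq$t) < 2)
    stop("continuity check needs at least 2 samples", call. = FALSE)
  if (any(diff(seq$t) < 0))
    stop("non-monotone times (beyond duplicates): invalid input", call. = FALSE)
  dts <- diff(seq$t)
  if (is.null(max_gap)) {
    pos <- dts[dts > 0]
    max_gap <- if (length(pos)) 3 * stats::median(pos) else Inf
  }
  if (is.null(max_jump))
    max_jump <- tryCatch(channel_defaults(seq$channel)$max_jump,
                         error = function(e) Inf)

  viol <- list()
  dvs <- diff(seq$v)
  dup <- which(dts == 0)
  dup_bad <- dup[!is.na(dvs[dup]) & dvs[dup] != 0]
  if (length(dup_bad))
    viol$dup <- data.frame(index = dup_bad, time = seq$t[dup_bad],
                           kind = "duplicate_time_jump")
  gaps <- which(dts > max_gap)
  if (length(gaps))
    viol$gap <- data.frame(index = gaps, time = seq$t[gaps], kind = "gap")
  miss <- which(is.na(seq$v))
  if (length(miss))
    viol$na <- data.frame(index = miss, time = seq$t[miss],
                          kind = "missing_value")
  jumps <- which(!is.na(dvs) & abs(dvs) > max_jump & dts > 0)
  if (length(jumps))
    viol$jump <- data.frame(index = jumps, time = seq$t[jumps],
                            kind = "value_jump")
  hold_jumps <- integer(0)
  if (mode == "hold") {
    hold_jumps <- which(!is.na(dvs) & dvs != 0)
    if (length(hold_jumps))
      viol$hold <- data.frame(index = hold_jumps, time = seq$t[hold_jumps],
                              kind = "hold_interpolate_jump")
  }

  failed <- character(0)
  if (length(gaps)) failed <- c(failed, "sampling_rate", "interpolable")
  if (length(miss)) failed <- union(failed, "interpolable")
  if (length(dup_bad) || length(jumps) || length(hold_jumps))
    failed <- union(failed, "no_jumps")
  violations <- if (length(viol)) do.call(rbind, unname(viol)) else
    data.frame(index = integer(0), time = numeric(0), kind = character(0))
  structure(
    list(continuous = length(failed) == 0, failed_conditions = failed,
         violations = violations, mode = mode,
         max_gap = max_gap, max_jump = max_jump),
    class = "continuity_report")
}

#' @rdname check_continuity
#' @export
check_continuity.tc_labeled <- function(seq, ...) {
  # nominal value domain: no subtraction, no order, no interpolate
  structure(
    list(continuous = FALSE, failed_conditions = "interpolable",
         violations = data.frame(index = NA_integer_, time = NA_real_,
                                 kind = "nominal_domain"),
         mode = NA_character_, max_gap = NA_real_, max_jump = NA_real_),
    class = "continuity_report")
}

#' @export
print.continuity_report <- function(x, ...) {
  cat(sprintf("<continuity_report> continuous=%s%s\n", x$continuous,
              if (length(x$failed_conditions))
                paste0("; failed: ",
                       paste(x$failed_conditions, collapse = ", "))
              else ""))
  if (nrow(x$violations)) {
    cat("  violations:", nrow(x$violations), "\n")
  }
  invisible(x)
}

#' Check sample-order preservation under an index-stable mechanism
#'
#' Given an original record and its anonymized image matched by sample
#' index, reports whether every originally ordered pair of sample times is
#' still ordered after anonymization. Time noise can swap neighbouring
#' samples; that is the order violation this detects.
#'
#' @param original a `tc_record`.
#' @param anonymized its index-stable image (`tc_sample_seq` or
#'   `tc_record`, same sample count).
#' @return list with `preserved` (logical) and `violations`, a two-column
#'   matrix of inverted index pairs `(i, k)`, `i < k` in the original but
#'   `t_i >= t_k` after anonymization (adjacent pairs reported).
#' @export
is_order_preserved <- function(original, anonymized) {
  stopifnot(inherits(original, "tc_sample_seq"),
            inherits(anonymized, "tc_sample_seq"))
  if (length(original$t) != length(anonymized$t))
    stop("sample-count mismatch: mechanisms under test must be index-stable",
         call. = FALSE)
  if (any(diff(original$t) <= 0))
    stop("original record must be strictly time-ordered", call. = FALSE)
  bad <- which(diff(anonymized$t) <= 0)
  violations <- cbind(i = bad, k = bad + 1L)
  list(preserved = length(bad) == 0L, violations = violations)
}
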