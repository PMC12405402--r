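#' Construct a raw sample sequence
#'
#' A sample sequence is the unvalidated form of a sampled physiological
#' signal: a list of `(t, v)` pairs in the order they were read from the
#' input, together with channel metadata. It deliberately admits duplicate
#' timestamps, gaps and out-of-domain values so that [check_continuity()]
#' and [tc_record()] can reject them explicitly rather than at parse time.
#'
#' @param t numeric vector of sample times in seconds from record start.
#' @param v numeric vector of sample values in the channel unit; `NA`
#'   denotes an explicitly missing (masked) value.
#' @param channel channel name, e.g. `"ECG"` (see [channel_defaults()]).
#' @param unit unit of `v`, e.g. `"mV"`.
#' @param domain length-2 numeric, the declared value-domain bounds
#'   `c(v_min, v_max)`.
#' @param fs_nominal nominal sampling frequency in Hz, or `NA`.
#' @param record_id record identifier string.
#' @param person_id optional ground-truth person identifier (or `NA`).
#' @return an object of class `tc_sample_seq`.
#' @seealso [tc_record()] for the validated form.
#' @export
tc_sample_seq <- function(t, v, channel = "ECG", unit = "mV",
                          domain = c(-Inf, Inf), fs_nominal = NA_real_,
                          record_id = "r1", person_id = NA_character_) {
  stopifnot(is.numeric(t), is.numeric(v), length(t) == length(v))
  if (any(!is.finite(t))) stop("sample times must be finite", call. = FALSE)
  if (any(!is.finite(v) & !is.na(v)))
    stop("sample values must be finite or NA (missing)", call. = FALSE)
  structure(
    list(t = as.numeric(t), v = as.numeric(v), channel = channel,
         unit = unit, domain = as.numeric(domain),
         fs_nominal = as.numeric(fs_nominal),
         record_id = as.character(record_id),
         person_id = as.character(person_id)),
    class = "tc_sample_seq")
}

#' Construct a validated time-continuous record
#'
#' A record is a sample sequence whose invariants hold: strictly increasing
#' times, at least two samples, and all non-missing values inside the
#' declared domain bounds. Duplicate timestamps carrying equal values are
#' collapsed with a warning; duplicates with differing values are rejected
#' (they are a continuity violation, not a representable record).
#'
#' Anonymization mechanisms may emit objects built with `validate = FALSE`:
#' index-stable noise on the time axis can break the ordering invariant, and
#' whether it does is precisely what [is_order_preserved()] measures.
#'
#' @inheritParams tc_sample_seq
#' @param validate if `FALSE`, skip invariant checks (used by mechanisms
#'   whose output may legitimately violate them).
#' @return an object of class `c("tc_record", "tc_sample_seq")`.
#' @export
tc_record <- function(t, v, channel = "ECG", unit = "mV",
                      domain = c(-Inf, Inf), fs_nominal = NA_real_,
                      record_id = "r1", person_id = NA_character_,
                      validate = TRUE) {
  x <- tc_sample_seq(t, v, channel, unit, domain, fs_nominal,
                     record_id, person_id)
  class(x) <- c("tc_record", class(x))
  if (validate) x <- validate_record(x)
  x
}

#' Validate record invariants
#'
#' Checks strict time ordering, minimum length and domain membership.
#' Duplicate timestamps with equal values are collapsed (warning); with
#' differing values an error is raised.
#'
#' @param x a `tc_sample_seq` or `tc_record`.
#' @return the validated object, classed as `tc_record`.
#' @export
validate_record <- function(x) {
  stopifnot(inherits(x, "tc_sample_seq"))
  if (length(x$t) >= 2 && any(diff(x$t) == 0)) {
    dup <- which(diff(x$t) == 0)
    if (any(x$v[dup] != x$v[dup + 1L], na.rm = TRUE))
      stop("duplicate timestamps with differing values: record is not a ",
           "valid time-continuous record", call. = FALSE)
    warning("collapsing ", length(dup), " duplicate timestamp(s) with ",
            "equal values", call. = FALSE)
    keep <- c(TRUE, diff(x$t) > 0)
    x$t <- x$t[keep]; x$v <- x$v[keep]
  }
  if (length(x$t) < 2) stop("a record needs at least 2 samples", call. = FALSE)
  if (any(diff(x$t) <= 0))
    stop("record times must be strictly increasing", call. = FALSE)
  bad <- !is.na(x$v) & (x$v < x$domain[1] | x$v > x$domain[2])
  if (any(bad))
    stop(sum(bad), " value(s) outside declared domain [",
         x$domain[1], ", ", x$domain[2], "]", call. = FALSE)
  if (!inherits(x, "tc_record")) class(x) <- c("tc_record", class(x))
  x
}

#' Per-channel defaults
#'
#' Default units, domain bounds and continuity jump tolerances for the
#' patient-monitor channels supported by the generator. The maximum
#' plausible per-step jump is application-specific; the ECG default of
#' 0.5 mV per sample step is the package's own choice.
#'
#' @param channel channel abbreviation (`"ECG"`, `"HF"`, `"Pulse"`,
#'   `"SPO2"`, `"BF"`, `"NIBP"`, `"IBP"`, `"PPG"`).
#' @return list with `unit`, `domain`, `max_jump`.
#' @export
channel_defaults <- function(channel = "ECG") {
  defs <- list(
    ECG   = list(unit = "mV",    domain = c(-5, 5),    max_jump = 0.5),
    HF    = list(unit = "bpm",   domain = c(0, 300),   max_jump = 30),
    Pulse = list(unit = "bpm",   domain = c(0, 300),   max_jump = 30),
    SPO2  = list(unit = "%",     domain = c(0, 100),   max_jump = 5),
    BF    = list(unit = "1/min", domain = c(0, 80),    max_jump = 10),
    NIBP  = list(unit = "mmHg",  domain = c(0, 300),   max_jump = 60),
    IBP   = list(unit = "mmHg",  domain = c(0, 300),   max_jump = 30),
    PPG   = list(unit = "a.u.",  domain = c(0, 1),     max_jump = 0.25))
  if (!channel %in% names(defs))
    stop("unknown channel: ", channel, call. = FALSE)
  defs[[channel]]
}

#' @export
print.tc_sample_seq <- function(x, ...) {
  kind <- if (inherits(x, "tc_record")) "tc_record" else "tc_sample_seq"
  cat(sprintf("<%s %s> channel=%s [%s], %d samples, t in [%.4g, %.4g] s\n",
              kind, x$record_id, x$channel, x$unit, length(x$t),
              if (length(x$t)) min(x$t) else NA,
              if (length(x$t)) max(x$t) else NA))
  if (!is.na(x$person_id)) cat("  person:", x$person_id, "\n")
  invisible(x)
}

#' @export
as.data.frame.tc_sample_seq <- function(x, ...) {
  data.frame(t = x$t, v = x$v)
}

#' @export
length.tc_sample_seq <- function(x) length(x$t)

#' Construct a database of records
#'
#' A database is a set of records keyed by their unique `record_id`, with
#' the per-record `person_id` fields serving as the optional ground-truth
#' mapping used by the attack-evaluation tools.
#'
#' @param records list of `tc_record` objects.
#' @return an object of class `tc_database`.
#' @export
tc_database <- function(records = list()) {
  stopifnot(all(vapply(records, inherits, logical(1), "tc_sample_seq")))
  ids <- vapply(records, function(r) r$record_id, character(1))
  if (anyDuplicated(ids)) stop("record_ids must be unique", call. = FALSE)
  names(records) <- ids
  structure(list(records = records), class = "tc_database")
}

#' @export
print.tc_database <- function(x, ...) {
  np <- length(unique(stats::na.omit(person_map(x))))
  cat(sprintf("<tc_database> %d records, %d known persons\n",
              length(x$records), np))
  invisible(x)
}

#' @export
length.tc_database <- function(x) length(x$records)

#' Ground-truth person mapping of a database
#'
#' @param db a `tc_database`.
#' @return named character vector `record_id -> person_id` (`NA` if unknown).
#' @export
person_map <- function(db) {
  stopifnot(inherits(db, "tc_database"))
  vapply(db$records, function(r) r$person_id, character(1))
}

#' Remove an individual from a database
#'
#' Returns the database without any record belonging to `person_id` — the
#' neighbouring database used by the privacy-ratio estimator.
#'
#' @param db a `tc_database`.
#' @param person_id person to remove.
#' @return a `tc_database`.
#' @export
drop_person <- function(db, person_id) {
  keep <- person_map(db) != person_id | is.na(person_map(db))
  tc_database(db$records[keep])
}
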