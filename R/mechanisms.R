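#' Bounded-noise perturbation specification
#'
#' Describes independent truncated-Laplace noise per axis. Perturbation of
#' physiological signals must be bounded — noise in the range of whole
#' volts or seconds would make an ECG clinically useless — so each axis
#' carries both a Laplace scale and a hard bound enforced by rejection
#' sampling. A scale or bound of 0 disables noise on that axis.
#'
#' @param axis which axes to perturb: `"value"`, `"time"` or `"both"`.
#' @param scale_v,scale_t Laplace scales (value units, seconds).
#' @param bound_v,bound_t hard noise bounds (value units, seconds);
#'   `Inf` leaves the Laplace noise unbounded.
#' @param seed default RNG seed.
#' @return list of class `noise_spec`.
#' @export
noise_spec <- function(axis = c("value", "time", "both"),
                       scale_v = 0, scale_t = 0,
                       bound_v = Inf, bound_t = Inf, seed = 1L) {
  axis <- match.arg(axis)
  stopifnot(scale_v >= 0, scale_t >= 0, bound_v >= 0, bound_t >= 0)
  structure(list(axis = axis, scale_v = scale_v, scale_t = scale_t,
                 bound_v = bound_v, bound_t = bound_t, seed = seed),
            class = "noise_spec")
}

#' Perturb a record with bounded Laplace noise
#'
#' Adds independent truncated-Laplace noise to each sample on the requested
#' axes. Values are clamped to the record's domain bounds afterwards; the
#' sample count is unchanged (the mechanism is index-stable) and the output
#' is deterministic per seed. Time noise may reorder samples — the output
#' is therefore returned without the ordering invariant enforced, and
#' [is_order_preserved()] measures whether order survived.
#'
#' @param rec a `tc_record`.
#' @param spec a [noise_spec()].
#' @param seed RNG seed; defaults to `spec$seed`.
#' @return a `tc_record` built with `validate = FALSE`.
#' @export
perturb_record <- function(rec, spec, seed = spec$seed) {
  stopifnot(inherits(rec, "tc_sample_seq"), inherits(spec, "noise_spec"))
  n <- length(rec$t)
  withr::with_seed(seed, {
    nt <- if (spec$axis %in% c("time", "both"))
      rlaplace_trunc(n, spec$scale_t, spec$bound_t) else numeric(n)
    nv <- if (spec$axis %in% c("value", "both"))
      rlaplace_trunc(n, spec$scale_v, spec$bound_v) else numeric(n)
    out <- rec
    out$t <- rec$t + nt
    out$v <- pmin(rec$domain[2], pmax(rec$domain[1], rec$v + nv))
    out
  })
}

#' Largest provably order-safe time-noise bound
#'
#' If every time perturbation satisfies `|noise| <= b` with
#' `b < min(dt)/2`, two samples can never swap: the worst case moves one
#' sample forward by `b` and its successor backward by `b`, closing a gap
#' of at most `2b < min(dt)`. Returns `min(dt)/2` minus a machine
#' tolerance; any [noise_spec()] with `bound_t` at or below this value
#' preserves order for every seed.
#'
#' @param rec a `tc_record` (>= 2 samples).
#' @return seconds.
#' @export
order_safe_time_bound <- function(rec) {
  stopifnot(inherits(rec, "tc_sample_seq"))
  if (length(rec$t) < 2) stop("need at least 2 samples", call. = FALSE)
  m <- min(diff(rec$t))
  m / 2 * (1 - 1e-9) - .Machine$double.eps
}

#' Differential-privacy parameters
#'
#' @param epsilon privacy budget (> 0).
#' @param sensitivity query sensitivity in value units (> 0).
#' @param clamp length-2 post-noise clamping range (defaults to the
#'   record's domain bounds at application time).
#' @param seed default RNG seed.
#' @return list of class `dp_params`.
#' @export
dp_params <- function(epsilon, sensitivity = 1, clamp = NULL, seed = 1L) {
  stopifnot(epsilon > 0, sensitivity > 0)
  structure(list(epsilon = epsilon, sensitivity = sensitivity,
                 clamp = clamp, seed = seed), class = "dp_params")
}

#' Pointwise epsilon-DP Laplace mechanism on the value axis
#'
#' Treats each sample independently and adds Laplace noise of scale
#' `sensitivity / epsilon` to its value, then clamps to `params$clamp`
#' (default: the record's domain bounds). Times are untouched, so the
#' mechanism is an endomorphism of the record's domain and continuity is
#' inherently preserved; note that the independent pointwise treatment
#' ignores temporal correlation, which is exactly the caveat this toolkit
#' is built to study.
#'
#' @param rec a `tc_record`.
#' @param params a [dp_params()].
#' @param seed RNG seed; defaults to `params$seed`.
#' @return a `tc_record` (ordering untouched, so invariants still hold).
#' @export
dp_pointwise_laplace <- function(rec, params, seed = params$seed) {
  stopifnot(inherits(rec, "tc_sample_seq"), inherits(params, "dp_params"))
  clamp <- if (is.null(params$clamp)) rec$domain else params$clamp
  withr::with_seed(seed, {
    out <- rec
    noise <- rlaplace(length(rec$v), params$sensitivity / params$epsilon)
    out$v <- pmin(clamp[2], pmax(clamp[1], rec$v + noise))
    out
  })
}

#' Time-generalization specification
#'
#' @param bin_width time-bin width in seconds (> 0).
#' @param representative how the bin representative is formed; currently
#'   `"midpoint_mean"`: time = bin midpoint, value = mean of bin values.
#' @return list of class `generalization_spec`.
#' @export
generalization_spec <- function(bin_width,
                                representative = "midpoint_mean") {
  stopifnot(bin_width > 0)
  structure(list(bin_width = bin_width, representative = representative),
            class = "generalization_spec")
}

#' Generalize a record along the time axis
#'
#' Groups samples into non-overlapping time bins of `bin_width` seconds
#' (anchored at the first sample) and emits one representative sample per
#' non-empty bin: the bin midpoint paired with the mean of the bin's
#' values. Because the bins are non-overlapping and ordered, the
#' representatives are always time-ordered — time generalization is
#' inherently order-safe.
#'
#' @param rec a `tc_record`.
#' @param spec a [generalization_spec()].
#' @return a `tc_record` of bin representatives.
#' @export
generalize_time <- function(rec, spec) {
  stopifnot(inherits(rec, "tc_sample_seq"),
            inherits(spec, "generalization_spec"))
  if (spec$bin_width < min(diff(rec$t)))
    warning("bin_width below the smallest time step: most bins hold a ",
            "single sample (no-op generalization)", call. = FALSE)
  bin <- floor((rec$t - rec$t[1]) / spec$bin_width)
  tg <- rec$t[1] + (unique(bin) + 0.5) * spec$bin_width
  vg <- as.numeric(tapply(rec$v, factor(bin, levels = unique(bin)), mean))
  out <- rec
  out$t <- tg
  out$v <- vg
  out$fs_nominal <- NA_real_
  out
}

#' Generalize a record to a nominal diagnosis label
#'
#' Maps a whole record to `(generalized time, nominal label)` — e.g. an
#' ECG to its diagnosis class. The output is deliberately *not* a record:
#' a nominal domain has no subtraction, absolute value or order, so no
#' interpolate exists and [check_continuity()] on the result reports
#' not-continuous. This is the executable witness that generalization is
#' not inherently continuity-safe.
#'
#' @param rec a `tc_record`.
#' @param labeler function `(rec, gt) -> character(1)`; default
#'   [default_labeler()].
#' @param gt optional `ecg_ground_truth` passed to the labeler.
#' @param time_bin width of the generalized time bin in seconds (default
#'   86400, one day).
#' @return list of class `tc_labeled` with `time_bin` (start of the
#'   containing bin), `label`, `record_id`.
#' @export
generalize_to_label <- function(rec, labeler = default_labeler, gt = NULL,
                                time_bin = 86400) {
  stopifnot(inherits(rec, "tc_sample_seq"))
  structure(list(time_bin = floor(rec$t[1] / time_bin) * time_bin,
                 label = labeler(rec, gt), record_id = rec$record_id),
            class = "tc_labeled")
}

#' Default diagnosis labeler
#'
#' A deliberately simple rule on the generator's ground truth, used to make
#' the continuity counterexample executable: myocardial infarction (`"MI"`)
#' if an ST-elevation event is present, cardiac arrhythmia (`"CA"`) if the
#' beat-to-beat jitter exceeds 10%, otherwise `"Healthy"`.
#'
#' @param rec a `tc_record` (unused by the default rule).
#' @param gt an `ecg_ground_truth` or `NULL`.
#' @return character(1) label.
#' @export
default_labeler <- function(rec, gt = NULL) {
  if (!is.null(gt)) {
    if ("st_elevation" %in% gt$events$event_type) return("MI")
    if (gt$params$rr_jitter > 0.10) return("CA")
  }
  "Healthy"
}

#' Swap one channel's records across individuals
#'
#' Randomly permutes which person the records of one channel are attached
#' to, leaving every record's internal samples untouched (so continuity and
#' order are trivially preserved). Cross-channel correlations are what this
#' destroys.
#'
#' @param db a `tc_database`.
#' @param attribute channel name to swap (must appear in >= 2 records).
#' @param seed RNG seed.
#' @return a `tc_database` with permuted `person_id` on that channel.
#' @export
swap_attribute <- function(db, attribute, seed = 1L) {
  stopifnot(inherits(db, "tc_database"))
  idx <- which(vapply(db$records, function(r) r$channel, character(1)) ==
                 attribute)
  if (length(idx) < 2)
    stop("attribute '", attribute, "' present in fewer than 2 records",
         call. = FALSE)
  withr::with_seed(seed, {
    recs <- db$records
    pids <- vapply(recs[idx], function(r) r$person_id, character(1))
    perm <- sample(seq_along(idx))
    for (j in seq_along(idx)) recs[[idx[j]]]$person_id <- pids[perm[j]]
    tc_database(recs)
  })
}

#' Suppress or mask parts of a database
#'
#' `suppress_record` deletes whole records; `suppress_attribute` deletes
#' every record of a channel; `mask` replaces a random fraction of each
#' selected record's values with the missing marker (`NA`), leaving times
#' intact.
#'
#' @param db a `tc_database`.
#' @param mode `"suppress_record"`, `"suppress_attribute"` or `"mask"`.
#' @param selector record ids (for `suppress_record`/`mask`) or a channel
#'   name (for `suppress_attribute`); `NULL` selects all records for
#'   `mask`.
#' @param mask_fraction fraction of samples to mask, in `[0, 1]`.
#' @param seed RNG seed for mask-site selection.
#' @return list with `db` (the redacted `tc_database`) and `report`
#'   (counts of removed records / masked samples).
#' @export
redact <- function(db, mode = c("suppress_record", "suppress_attribute",
                                "mask"),
                   selector = NULL, mask_fraction = 0, seed = 1L) {
  mode <- match.arg(mode)
  stopifnot(inherits(db, "tc_database"))
  if (mode == "mask" && (mask_fraction < 0 || mask_fraction > 1))
    stop("mask_fraction must be in [0, 1]", call. = FALSE)
  recs <- db$records
  if (mode == "suppress_record") {
    removed <- intersect(names(recs), selector)
    recs <- recs[setdiff(names(recs), removed)]
    return(list(db = tc_database(recs),
                report = list(removed_records = length(removed),
                              masked_samples = 0L)))
  }
  if (mode == "suppress_attribute") {
    is_sel <- vapply(recs, function(r) r$channel %in% selector, logical(1))
    return(list(db = tc_database(recs[!is_sel]),
                report = list(removed_records = sum(is_sel),
                              masked_samples = 0L)))
  }
  sel <- if (is.null(selector)) names(recs) else
    intersect(names(recs), selector)
  masked <- 0L
  withr::with_seed(seed, {
    for (id in sel) {
      n <- length(recs[[id]]$v)
      k <- round(mask_fraction * n)
      if (k > 0) {
        recs[[id]]$v[sample.int(n, k)] <- NA_real_
        masked <- masked + k
      }
    }
  })
  list(db = tc_database(recs),
       report = list(removed_records = 0L, masked_samples = masked))
}
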