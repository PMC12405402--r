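#' Inter-beat-interval linkage attack
#'
#' Links records by their characteristic inter-event timing: the attacker
#' detects R peaks in a reference record known to belong to the victim,
#' takes the median inter-R interval `dt_a`, and collects the candidate
#' set `E` of database records whose own median inter-R interval lies
#' within the tolerance band `|dt_i - dt_a| <= eps_delta`. The candidate
#' set can be narrowed to the verified set `E_v` by a morphological
#' feature — classically the presence of a U wave, which not every person
#' exhibits.
#'
#' @param reference a `tc_record` known to belong to the victim.
#' @param db a `tc_database` of (possibly anonymized) records.
#' @param eps_delta timing tolerance in seconds.
#' @param verify_feature `NULL`, or `"u_wave"` to keep only candidates
#'   exhibiting a U wave (when the reference does), or an event type name
#'   to require that event in the candidate's detected events.
#' @param config a [detector_config()].
#' @return list of class `linkage_result`: `E` (candidate record ids),
#'   `E_v` (verified subset), `eps_delta`, `dt_reference`, `dt_candidates`.
#' @export
delta_t_link <- function(reference, db, eps_delta = 0.01,
                         verify_feature = NULL,
                         config = detector_config()) {
  stopifnot(inherits(reference, "tc_sample_seq"), inherits(db, "tc_database"))
  ref_ev <- tryCatch(detect_events(reference, config), error = function(e)
    stop("attack inapplicable: no events detectable in reference record",
         call. = FALSE))
  rp <- ref_ev$time[ref_ev$event_type == "r_peak"]
  if (length(rp) < 2)
    stop("attack inapplicable: fewer than 2 events in reference record",
         call. = FALSE)
  dt_a <- stats::median(diff(rp))

  dts <- rep(NA_real_, length(db$records))
  names(dts) <- names(db$records)
  feats <- logical(length(db$records))
  names(feats) <- names(db$records)
  for (id in names(db$records)) {
    ev <- tryCatch(detect_events(db$records[[id]], config),
                   error = function(e) NULL)
    if (is.null(ev)) next
    rpi <- ev$time[ev$event_type == "r_peak"]
    if (length(rpi) >= 2) dts[id] <- stats::median(diff(rpi))
    feats[id] <- if (is.null(verify_feature)) TRUE
    else if (verify_feature == "u_wave") isTRUE(attr(ev, "u_present"))
    else verify_feature %in% ev$event_type
  }
  E <- names(dts)[!is.na(dts) & abs(dts - dt_a) <= eps_delta]
  E_v <- E[feats[E]]
  structure(list(E = E, E_v = E_v, eps_delta = eps_delta,
                 dt_reference = dt_a, dt_candidates = dts),
            class = "linkage_result")
}

#' Event-signature linkage between two records
#'
#' Builds the event signature (the time-ordered sequence of detected
#' diagnostic event types, R peaks excluded) of each record and links the
#' records when the edit distance between the signatures is at most
#' `threshold`.
#'
#' @param r1,r2 `tc_record`s.
#' @param threshold maximum edit distance for a link.
#' @param config a [detector_config()].
#' @return list with `linked`, `distance`, `sig1`, `sig2` and
#'   `vacuous` (`TRUE` when both signatures are empty, in which case the
#'   records link at distance 0 vacuously).
#' @export
signature_link <- function(r1, r2, threshold = 1,
                           config = detector_config()) {
  sig <- function(r) {
    ev <- detect_events(r, config)
    ev$event_type[ev$event_type != "r_peak"]
  }
  s1 <- sig(r1); s2 <- sig(r2)
  d <- edit_distance(s1, s2)
  list(linked = d <= threshold, distance = d, sig1 = s1, sig2 = s2,
       vacuous = length(s1) == 0 && length(s2) == 0)
}

#' Score a linkage attack against ground truth
#'
#' Runs the inter-beat-timing attack with every database record in turn as
#' the reference and predicts a link for every (reference, candidate) pair
#' with distinct record ids. Predicted pairs are scored against the true
#' same-person pairs from the ground-truth mapping.
#'
#' @param db a `tc_database` whose records carry `person_id` ground truth
#'   (or pass `ground_truth` explicitly).
#' @param db_anonymized optionally, the anonymized database the attacker
#'   actually sees (defaults to `db`); references are drawn from `db`
#'   (attacker background knowledge), candidates from `db_anonymized`.
#' @param eps_delta,verify_feature,config passed to [delta_t_link()].
#' @param ground_truth named `record_id -> person_id` vector.
#' @param use_verified score the verified set `E_v` instead of `E`.
#' @return list with `precision` (`NA` when nothing was predicted),
#'   `recall`, `tp`, `fp`, `fn`, `predicted` (data frame of predicted
#'   pairs).
#' @export
attack_evaluate <- function(db, db_anonymized = db, eps_delta = 0.01,
                            verify_feature = NULL,
                            config = detector_config(),
                            ground_truth = person_map(db),
                            use_verified = FALSE) {
  ids <- names(db$records)
  if (any(is.na(ground_truth[ids])))
    stop("ground truth must cover all records", call. = FALSE)
  pred <- list()
  for (id in ids) {
    lr <- tryCatch(
      delta_t_link(db$records[[id]], db_anonymized, eps_delta,
                   verify_feature, config),
      error = function(e) NULL)
    if (is.null(lr)) next
    cand <- setdiff(if (use_verified) lr$E_v else lr$E, id)
    if (length(cand))
      pred[[id]] <- data.frame(ref = id, linked = cand)
  }
  pred <- if (length(pred)) do.call(rbind, pred) else
    data.frame(ref = character(0), linked = character(0))
  rownames(pred) <- NULL
  key <- function(x, y) paste(pmin(x, y), pmax(x, y))
  pred_keys <- unique(key(pred$ref, pred$linked))
  truth <- expand.grid(a = ids, b = ids, stringsAsFactors = FALSE)
  truth <- truth[truth$a < truth$b &
                   ground_truth[truth$a] == ground_truth[truth$b], ]
  true_keys <- key(truth$a, truth$b)
  tp <- length(intersect(pred_keys, true_keys))
  fp <- length(setdiff(pred_keys, true_keys))
  fn <- length(setdiff(true_keys, pred_keys))
  list(precision = if (length(pred_keys)) tp / (tp + fp) else NA_real_,
       recall = if (length(true_keys)) tp / (tp + fn) else NA_real_,
       tp = tp, fp = fp, fn = fn, predicted = pred)
}

#' Monte-Carlo privacy-ratio estimate
#'
#' Estimates the privacy level of an individual `i` in database `S` as the
#' ratio `P = Pr(S \\ i, i) / Pr(S, i)` of an attacker's decision-success
#' probabilities without and with the individual's records present.
#' Removing an individual cannot add information about them, so `P <= 1`;
#' values near 1 mean the database leaks little about `i`. The
#' probabilities are estimated as Monte-Carlo success frequencies of an
#' explicit decision procedure over `trials` anonymize-and-attack runs
#' with fresh derived seeds — one admissible instantiation of the
#' abstract decision probabilities, which are application-specific.
#'
#' @param decision function `(db_anonymized, person_id, trial_seed) ->
#'   logical`, the attacker's decision procedure about `i`; the default
#'   claims membership when some record's median inter-R interval matches
#'   a raw reference record of `i` within `eps_delta`.
#' @param db a `tc_database` containing records of `person_id`.
#' @param person_id the individual under assessment.
#' @param mechanism function `(db, seed) -> tc_database`, the anonymizer
#'   applied before each attack (identity by default).
#' @param trials Monte-Carlo trials per side.
#' @param seed master seed.
#' @param eps_delta tolerance of the default decision procedure.
#' @param epsilon,a nominal privacy budget and query allowance recorded in
#'   the estimate (documentation fields; the attack itself queries the
#'   released database directly).
#' @return list of class `privacy_estimate`: `p_with`, `p_without`, their
#'   Wilson standard errors, `ratio`, `ratio_se`, `undefined` flag,
#'   `trials`.
#' @export
privacy_ratio <- function(db, person_id, decision = NULL,
                          mechanism = function(d, seed) d,
                          trials = 50, seed = 1L, eps_delta = 0.01,
                          epsilon = NA_real_, a = 1L) {
  stopifnot(inherits(db, "tc_database"))
  pm <- person_map(db)
  if (!person_id %in% pm)
    stop("individual not present in database", call. = FALSE)
  ref_id <- names(pm)[pm == person_id][1]
  reference <- db$records[[ref_id]]
  if (is.null(decision))
    decision <- function(d_anon, pid, s) {
      lr <- tryCatch(delta_t_link(reference, d_anon, eps_delta),
                     error = function(e) NULL)
      !is.null(lr) && length(lr$E) > 0
    }
  db_wo <- drop_person(db, person_id)
  run <- function(base_db, offset) {
    succ <- logical(trials)
    for (k in seq_len(trials)) {
      s <- derive_seed(seed, offset + k)
      succ[k] <- isTRUE(decision(mechanism(base_db, s), person_id, s))
    }
    mean(succ)
  }
  p_with <- run(db, 0L)
  p_without <- run(db_wo, trials)
  # Wilson-interval half-width divided by z: a standard error that stays
  # positive at the boundary estimates 0 and 1
  wilson_se <- function(p, n, z = 1.96) {
    (z / (1 + z^2 / n) * sqrt(p * (1 - p) / n + z^2 / (4 * n^2))) / z
  }
  se_w <- wilson_se(p_with, trials)
  se_wo <- wilson_se(p_without, trials)
  undefined <- p_with == 0
  ratio <- if (undefined) NA_real_ else p_without / p_with
  ratio_se <- if (undefined || p_without == 0) NA_real_ else
    ratio * sqrt((se_w / p_with)^2 + (se_wo / p_without)^2)
  structure(list(epsilon = epsilon, a = a, p_with = p_with,
                 p_without = p_without, se_with = se_w, se_without = se_wo,
                 ratio = ratio, ratio_se = ratio_se,
                 undefined = undefined, trials = trials),
            class = "privacy_estimate")
}

#' @export
print.privacy_estimate <- function(x, ...) {
  cat(sprintf(paste0("<privacy_estimate> p_with=%.3f (se %.3f), ",
                     "p_without=%.3f (se %.3f), ratio=%s (%d trials)\n"),
              x$p_with, x$se_with, x$p_without, x$se_without,
              if (x$undefined) "undefined" else sprintf("%.3f", x$ratio),
              x$trials))
  invisible(x)
}
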