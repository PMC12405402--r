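#' Empirically verify a preservation property of a mechanism
#'
#' Runs an index-stable mechanism repeatedly over a corpus of valid
#' records and counts violations of a preservation property, turning the
#' formal safety statements about mechanism classes into an executable
#' check. Properties:
#' \describe{
#'   \item{`continuity`}{the anonymized output still admits a jump-free
#'     interpolation on its domain. Checked with [check_continuity()] at
#'     `max_jump = Inf`: the property concerns the domain (does an
#'     interpolate exist at all?), not clinical jump plausibility, so a
#'     nominal-label output fails while arbitrarily noisy numeric output
#'     on the same domain does not. Time-reordered output is sorted
#'     before the check, as ordering is scored separately.}
#'   \item{`order`}{[is_order_preserved()] between input and output.}
#'   \item{`step_characteristics`}{the mean sampling step of the output is
#'     within `step_tol` (default 5%) of the input's.}
#' }
#'
#' @param mechanism function `(record, seed) -> record-like` (a
#'   `tc_sample_seq`, `tc_record` or `tc_labeled`).
#' @param property one of `"continuity"`, `"order"`,
#'   `"step_characteristics"`.
#' @param corpus a `tc_database` of valid records.
#' @param trials number of repetitions (each with a fresh derived seed).
#' @param seed master seed.
#' @param expected `"guaranteed"` or `"not_guaranteed"`, from the theory.
#' @param mechanism_id label for the report.
#' @param step_tol relative tolerance for `step_characteristics`.
#' @return list of class `property_report` with `mechanism`, `property`,
#'   `trials` (total record applications), `violations`, `verdict`
#'   (`"always_held"` or `"violated"`), `expected`, `matches_expected`.
#' @export
verify_mechanism_property <- function(mechanism,
                                      property = c("continuity", "order",
                                                   "step_characteristics"),
                                      corpus, trials = 100, seed = 1L,
                                      expected = c("guaranteed",
                                                   "not_guaranteed"),
                                      mechanism_id = "mechanism",
                                      step_tol = 0.05) {
  property <- match.arg(property)
  expected <- match.arg(expected)
  stopifnot(inherits(corpus, "tc_database"))
  violations <- 0L
  total <- 0L
  for (k in seq_len(trials)) {
    for (j in seq_along(corpus$records)) {
      rec <- corpus$records[[j]]
      out <- mechanism(rec, derive_seed(seed, k * 1000L + j))
      total <- total + 1L
      bad <- switch(property,
        continuity = {
          if (inherits(out, "tc_labeled")) {
            !check_continuity(out)$continuous
          } else {
            o <- out
            ord <- order(o$t)
            o$t <- o$t[ord]; o$v <- o$v[ord]
            # collapse coincident times created by time noise
            keep <- c(TRUE, diff(o$t) > 0)
            o$t <- o$t[keep]; o$v <- o$v[keep]
            !check_continuity(o, mode = "linear",
                              max_jump = Inf)$continuous
          }
        },
        order = {
          if (inherits(out, "tc_labeled")) TRUE
          else if (length(out$t) != length(rec$t))
            any(diff(out$t) <= 0) # non-index-stable (e.g. bin representatives)
          else !is_order_preserved(rec, out)$preserved
        },
        step_characteristics = {
          if (inherits(out, "tc_labeled") || length(out$t) < 2) TRUE
          else {
            abs(mean(diff(out$t)) - mean(diff(rec$t))) >
              step_tol * mean(diff(rec$t))
          }
        })
      if (isTRUE(bad)) violations <- violations + 1L
    }
  }
  verdict <- if (violations == 0L) "always_held" else "violated"
  structure(list(mechanism = mechanism_id, property = property,
                 trials = total, violations = violations,
                 verdict = verdict, expected = expected,
                 matches_expected = (expected == "guaranteed") ==
                   (violations == 0L)),
            class = "property_report")
}

#' @export
print.property_report <- function(x, ...) {
  cat(sprintf("<property_report> %s x %s: %d/%d violations -> %s (expected %s)%s\n",
              x$mechanism, x$property, x$violations, x$trials, x$verdict,
              x$expected, if (x$matches_expected) "" else "  ** MISMATCH **"))
  invisible(x)
}

#' Run the full mechanism-property verification matrix
#'
#' Exercises the reference mechanisms against the continuity and order
#' preservation properties and compares the empirical outcome with the
#' theoretical expectation: time generalization preserves order
#' (non-overlapping bins); swapping preserves both order and continuity
#' (samples untouched); value perturbation and pointwise DP preserve
#' continuity (domain endomorphisms); time perturbation bounded at or
#' below [order_safe_time_bound()] preserves order; unbounded time
#' perturbation with scale comparable to the sampling step does not
#' (witnessed violations); and generalization to a nominal label does not
#' preserve continuity (witnessed on every trial). `"guaranteed"` rows
#' must show zero violations over the trial budget; `"not_guaranteed"`
#' rows must produce at least one witnessed violation.
#'
#' @param corpus a `tc_database`; default is a small generated ECG corpus.
#' @param trials trials per matrix row.
#' @param seed master seed.
#' @return data frame with one row per (mechanism, property) pair:
#'   `mechanism`, `property`, `expected`, `trials`, `violations`,
#'   `verdict`, `matches_expected`.
#' @export
theorem_matrix <- function(corpus = NULL, trials = 100, seed = 1L) {
  if (is.null(corpus)) {
    g <- lapply(1:3, function(i)
      generate_ecg(ecg_params(fs = 250, heart_rate = 55 + 10 * i),
                   n_cycles = 4, seed = derive_seed(seed, i),
                   record_id = paste0("c", i),
                   person_id = paste0("p", i))$record)
    corpus <- tc_database(g)
  }
  any_rec <- corpus$records[[1]]
  mdt <- mean(diff(any_rec$t))
  safe_b <- min(vapply(corpus$records, order_safe_time_bound, numeric(1)))

  mechs <- list(
    generalize_time = function(rec, s)
      generalize_time(rec, generalization_spec(bin_width = 0.05)),
    swap = local({
      # db-level mechanism: permuting whole records across persons leaves
      # each record's samples untouched; verify on the swapped records
      function(rec, s) {
        db <- swap_attribute(corpus, rec$channel, seed = s)
        db$records[[rec$record_id]]
      }
    }),
    perturb_value = function(rec, s)
      perturb_record(rec, noise_spec("value", scale_v = 0.2,
                                     bound_v = 0.6), seed = s),
    dp_laplace = function(rec, s)
      dp_pointwise_laplace(rec, dp_params(epsilon = 1, sensitivity = 0.1),
                           seed = s),
    perturb_time_bounded = function(rec, s)
      perturb_record(rec, noise_spec("time", scale_t = safe_b / 2,
                                     bound_t = safe_b), seed = s),
    perturb_time_unbounded = function(rec, s)
      perturb_record(rec, noise_spec("time", scale_t = mdt,
                                     bound_t = Inf), seed = s),
    generalize_label = function(rec, s) generalize_to_label(rec))

  rows <- list(
    list("generalize_time", "order", "guaranteed"),
    list("swap", "order", "guaranteed"),
    list("swap", "continuity", "guaranteed"),
    list("perturb_value", "continuity", "guaranteed"),
    list("dp_laplace", "continuity", "guaranteed"),
    list("perturb_time_bounded", "order", "guaranteed"),
    list("perturb_time_unbounded", "order", "not_guaranteed"),
    list("generalize_label", "continuity", "not_guaranteed"))

  out <- lapply(seq_along(rows), function(i) {
    r <- rows[[i]]
    pr <- verify_mechanism_property(mechs[[r[[1]]]], r[[2]], corpus,
                                    trials = trials,
                                    seed = derive_seed(seed, 100L + i),
                                    expected = r[[3]],
                                    mechanism_id = r[[1]])
    data.frame(mechanism = pr$mechanism, property = pr$property,
               expected = pr$expected, trials = pr$trials,
               violations = pr$violations, verdict = pr$verdict,
               matches_expected = pr$matches_expected)
  })
  do.call(rbind, out)
}
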