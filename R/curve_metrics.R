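#' Curve-norm parameters
#'
#' @param p norm order, `2 <= p < Inf`.
#' @param resample_fs resampling frequency in Hz before the Fourier
#'   transform; `NULL` uses 4x the curve's nominal sampling rate (or 4x
#'   the reciprocal median step when no nominal rate is declared).
#' @return list of class `norm_params`.
#' @export
norm_params <- function(p = 2, resample_fs = NULL) {
  stopifnot(p >= 2, is.finite(p))
  structure(list(p = p, resample_fs = resample_fs), class = "norm_params")
}

.norm_fs <- function(x, params) {
  if (!is.null(params$resample_fs)) return(params$resample_fs)
  cv <- as_curve(x)
  fs0 <- if (inherits(x, "tc_sample_seq") && is.finite(x$fs_nominal))
    x$fs_nominal else 1 / stats::median(diff(cv$t))
  4 * fs0
}

#' Fourier curve norm
#'
#' Maps a curve to the vector of its frequencies and applies a p-norm:
#' the curve is resampled (linear interpolate) onto an equidistant grid,
#' transformed with the unnormalized forward discrete Fourier transform,
#' and the p-norm of the coefficient magnitudes is returned. For `p = 2`
#' Parseval's identity gives `|c| = sqrt(n) * ||values||_2`, which the test
#' suite asserts to 1e-9 relative. The norm is 0 iff all values are 0.
#'
#' @param c a curve.
#' @param params a [norm_params()].
#' @return non-negative scalar.
#' @export
curve_norm <- function(c, params = norm_params()) {
  stopifnot(inherits(params, "norm_params"))
  rs <- resample_curve(c, .norm_fs(c, params))
  sum(Mod(stats::fft(rs$v))^params$p)^(1 / params$p)
}

#' Mismatch-correction parameters
#'
#' @param tau maximum total corrected fraction of the common duration,
#'   in `[0, 1]`.
#' @param omega maximum width of a single corrected region, in seconds.
#' @return list of class `correction_params`.
#' @export
correction_params <- function(tau = 0.05, omega = 0.1) {
  stopifnot(tau >= 0, tau <= 1, omega > 0)
  structure(list(tau = tau, omega = omega), class = "correction_params")
}

#' Correct small mismatch regions between two curves
#'
#' A handful of non-matching spikes or valleys can inflate any max-based
#' curve distance. This operator scores sliding windows of width at most
#' `omega` by their mean absolute value difference, then greedily excises
#' the worst non-overlapping windows while the total excised duration stays
#' within `tau` times the common duration, replacing each excised span in
#' *both* curves by a straight bridge between its edge samples. Both
#' curves are first resampled to a shared equidistant grid over their
#' common time support.
#'
#' @param x,y curves with overlapping time support.
#' @param params a [correction_params()].
#' @param grid_fs grid frequency for the common resampling; default is the
#'   reciprocal median step of `x`.
#' @return list with corrected curves `x`, `y` (as `list(t, v)`) and
#'   `regions`, a data frame of excised spans (`start`, `end`, `score`).
#' @export
region_correct_E <- function(x, y, params = correction_params(),
                             grid_fs = NULL) {
  stopifnot(inherits(params, "correction_params"))
  a <- as_curve(x); b <- as_curve(y)
  lo <- max(min(a$t), min(b$t)); hi <- min(max(a$t), max(b$t))
  if (lo >= hi)
    stop("curves have disjoint time support", call. = FALSE)
  if (is.null(grid_fs)) grid_fs <- 1 / stats::median(diff(a$t))
  ga <- resample_curve(a, grid_fs, c(lo, hi))
  gb <- resample_curve(b, grid_fs, c(lo, hi))
  tt <- ga$t; n <- length(tt)
  regions <- data.frame(start = numeric(0), end = numeric(0),
                        score = numeric(0))
  if (params$tau > 0) {
    dt <- 1 / grid_fs
    wlen <- max(1L, min(n - 1L, floor(params$omega / dt)))
    step <- max(1L, floor(wlen / 2))
    starts <- unique(c(seq(1L, n - wlen, by = step), n - wlen))
    starts <- starts[starts >= 1L]
    mism <- abs(ga$v - gb$v)
    cm <- c(0, cumsum(mism))
    score <- (cm[starts + wlen] - cm[starts]) / wlen
    ord <- order(score, decreasing = TRUE)
    budget <- params$tau * (hi - lo)
    used <- logical(n)
    total <- 0
    picked <- list()
    for (k in ord) {
      i0 <- starts[k]; i1 <- starts[k] + wlen - 1L
      if (any(used[i0:i1])) next
      span <- tt[i1] - tt[i0] + dt
      if (total + span > budget) next
      if (score[k] <= 0) break
      used[i0:i1] <- TRUE
      total <- total + span
      picked[[length(picked) + 1L]] <- c(i0, i1, score[k])
    }
    if (length(picked)) {
      # merge adjacent excisions, then bridge both curves linearly
      used_idx <- sort(unique(unlist(lapply(picked, function(p)
        p[1]:p[2]))))
      runs <- split(used_idx, cumsum(c(1, diff(used_idx) != 1)))
      for (r in runs) {
        i0 <- min(r); i1 <- max(r)
        l <- max(1L, i0 - 1L); rgt <- min(n, i1 + 1L)
        idx <- i0:i1
        w <- if (tt[rgt] > tt[l]) (tt[idx] - tt[l]) / (tt[rgt] - tt[l])
             else rep(0, length(idx))
        ga$v[idx] <- ga$v[l] + w * (ga$v[rgt] - ga$v[l])
        gb$v[idx] <- gb$v[l] + w * (gb$v[rgt] - gb$v[l])
        regions <- rbind(regions, data.frame(
          start = tt[i0], end = tt[i1],
          score = mean(mism[idx])))
      }
      regions <- regions[order(regions$start), ]
      rownames(regions) <- NULL
    }
  }
  list(x = ga, y = gb, regions = regions)
}

#' Alignment (transform) family for curve comparison
#'
#' The restricted family of transforms searched when aligning one curve to
#' another before a Fréchet measurement — the computable stand-in for the
#' Gromov–Hausdorff idea of quotienting out isometric embeddings.
#' Rotation is excluded on purpose: rotating a time series would mix axes
#' with different units. An empty `transforms` vector means the identity.
#'
#' @param transforms subset of `c("time_shift", "value_offset",
#'   "value_scale")`.
#' @param time_shift_range,value_offset_range,value_scale_range numeric
#'   length-2 search ranges; `NULL` derives them from the data.
#' @param grid_n coarse-grid points per active parameter.
#' @param refine run a local optimizer from the best grid point.
#' @return list of class `alignment_family`.
#' @export
alignment_family <- function(transforms = c("time_shift", "value_offset"),
                             time_shift_range = NULL,
                             value_offset_range = NULL,
                             value_scale_range = c(0.5, 2),
                             grid_n = 9, refine = TRUE) {
  ok <- c("time_shift", "value_offset", "value_scale")
  if (!all(transforms %in% ok))
    stop("unknown transform(s): ",
         paste(setdiff(transforms, ok), collapse = ", "), call. = FALSE)
  structure(list(transforms = transforms,
                 time_shift_range = time_shift_range,
                 value_offset_range = value_offset_range,
                 value_scale_range = value_scale_range,
                 grid_n = grid_n, refine = refine),
            class = "alignment_family")
}

.apply_transform <- function(cv, par) {
  list(t = cv$t + par[["time_shift"]],
       v = par[["value_scale"]] * cv$v + par[["value_offset"]])
}

#' Align one curve to another over a transform family
#'
#' Transforms `x` as close to `y` as possible, minimizing the discrete
#' Fréchet distance over the family by a coarse grid search followed by
#' local Nelder-Mead (or golden-section for a single parameter)
#' refinement. With an empty family `x` is returned unchanged under the
#' identity transform.
#'
#' @param x,y curves.
#' @param family an [alignment_family()].
#' @param standardize passed to [discrete_frechet()].
#' @return list with `curve` (transformed `x` as `list(t, v)`), `params`
#'   (named transform parameters), `distance` (the achieved Fréchet
#'   distance).
#' @export
align_G <- function(x, y, family = alignment_family(),
                    standardize = FALSE) {
  stopifnot(inherits(family, "alignment_family"))
  a <- as_curve(x); b <- as_curve(y)
  identity_par <- c(time_shift = 0, value_offset = 0, value_scale = 1)
  act <- family$transforms
  if (!length(act))
    return(list(curve = a, params = as.list(identity_par),
                distance = discrete_frechet(a, b,
                                            standardize = standardize)))
  ranges <- list(
    time_shift = family$time_shift_range %||%
      (c(-1, 1) * (max(b$t) - min(b$t)) / 4),
    value_offset = family$value_offset_range %||%
      (mean(b$v) - mean(a$v) + c(-1, 1) * max(diff(range(b$v)),
                                              .Machine$double.eps)),
    value_scale = family$value_scale_range)
  obj <- function(p) {
    par <- identity_par
    par[act] <- p
    discrete_frechet(.apply_transform(a, par), b,
                     standardize = standardize)
  }
  grids <- lapply(ranges[act], function(r)
    seq(r[1], r[2], length.out = family$grid_n))
  grid <- as.matrix(expand.grid(grids))
  vals <- apply(grid, 1, obj)
  best <- grid[which.min(vals), ]
  if (family$refine) {
    fit <- if (length(act) == 1L)
      stats::optim(best, obj, method = "Brent",
                   lower = ranges[[act]][1], upper = ranges[[act]][2])
    else
      stats::optim(best, obj, method = "Nelder-Mead",
                   control = list(maxit = 200))
    if (fit$value <= min(vals)) best <- fit$par
  }
  par <- identity_par
  par[act] <- best
  list(curve = .apply_transform(a, par), params = as.list(par),
       distance = obj(best))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Region-corrected, aligned curve difference
#'
#' The composite curve difference `d(c1, c2, tau, omega) =
#' F(G(E(c1, c2, tau, omega), c2), c2)`: small mismatch regions are first
#' corrected in both curves ([region_correct_E()]), the corrected first
#' curve is aligned to the corrected second over the transform family
#' ([align_G()]), and the discrete Fréchet distance of the result is
#' returned. It is non-negative and zero for identical curves.
#'
#' @param c1,c2 curves.
#' @param params a [correction_params()].
#' @param family an [alignment_family()]; default identity (empty family).
#' @param grid_fs,standardize passed to the components.
#' @return scalar distance with attributes `"regions"` (corrected spans)
#'   and `"transform"` (alignment parameters).
#' @export
curve_difference <- function(c1, c2, params = correction_params(),
                             family = alignment_family(character(0)),
                             grid_fs = NULL, standardize = FALSE) {
  e <- region_correct_E(c1, c2, params, grid_fs = grid_fs)
  g <- align_G(e$x, e$y, family, standardize = standardize)
  d <- discrete_frechet(g$curve, e$y, standardize = standardize)
  attr(d, "regions") <- e$regions
  attr(d, "transform") <- g$params
  d
}

#' Pair raw and anonymized records for utility measurement
#'
#' Matches records of two databases by shared `record_id` (a bijection on
#' the shared ids).
#'
#' @param db_raw,db_anon `tc_database`s (or plain lists of curves).
#' @return list of class `paired_results`: each element holds `c1` (raw)
#'   and `c2` (anonymized).
#' @export
pair_records <- function(db_raw, db_anon) {
  r1 <- if (inherits(db_raw, "tc_database")) db_raw$records else db_raw
  r2 <- if (inherits(db_anon, "tc_database")) db_anon$records else db_anon
  ids <- intersect(names(r1), names(r2))
  if (!length(ids)) stop("no shared record ids to pair", call. = FALSE)
  structure(lapply(ids, function(id) list(id = id, c1 = r1[[id]],
                                          c2 = r2[[id]])),
            class = "paired_results")
}

#' Time-continuous mean relative error
#'
#' The MRE adapted to curves: with per-pair curve differences
#' `d_i = d(c1_i, c2_i, tau, omega)` and curve norms `|c1_i|`, the metric
#' is `(1 / N) * sum_i d_i / |c1_i|` with the normalizer `N = sum_i d_i`.
#' When every pair is identical, `N = 0` and the error is 0 by convention
#' (flagged in the `"all_identical"` attribute); a raw curve with zero
#' norm is an error. Note the algebraic consequence of the normalization:
#' for a single pair with `d > 0` the result is exactly `1 / |c1|`,
#' independent of `d`.
#'
#' @param pairs a [pair_records()] result.
#' @param params a [correction_params()].
#' @param family an [alignment_family()].
#' @param norm a [norm_params()].
#' @param ... passed to [curve_difference()].
#' @return scalar; attribute `"components"` holds the per-pair `d` and
#'   norms.
#' @export
tc_mre <- function(pairs, params = correction_params(),
                   family = alignment_family(character(0)),
                   norm = norm_params(), ...) {
  stopifnot(inherits(pairs, "paired_results"), length(pairs) >= 1)
  d <- vapply(pairs, function(p)
    as.numeric(curve_difference(p$c1, p$c2, params, family, ...)),
    numeric(1))
  nrm <- vapply(pairs, function(p) curve_norm(p$c1, norm), numeric(1))
  if (any(nrm == 0))
    stop("undefined: a raw curve has zero norm", call. = FALSE)
  N <- sum(d)
  if (N == 0) {
    out <- 0
    attr(out, "all_identical") <- TRUE
  } else {
    out <- sum(d / nrm) / N
    attr(out, "all_identical") <- FALSE
  }
  attr(out, "components") <- data.frame(
    id = vapply(pairs, function(p) p$id, character(1)),
    d = d, norm = nrm)
  out
}

#' Decision utility of a mechanism on a record
#'
#' A decision made on the raw record is treated as correct by definition;
#' the utility of a mechanism for a set of discrete decisions is the
#' fraction of decisions unchanged by anonymization:
#' `U = (1/|D|) * sum_d [d(e) == d(alpha(e))]`.
#'
#' @param decisions non-empty named list of functions `record -> discrete
#'   outcome`.
#' @param record a `tc_record`.
#' @param mechanism function `record -> anonymized record`.
#' @return fraction in `[0, 1]`; attribute `"per_decision"` details.
#' @export
decision_utility <- function(decisions, record, mechanism) {
  if (!length(decisions)) stop("empty decision set", call. = FALSE)
  anon <- mechanism(record)
  same <- vapply(decisions, function(d)
    identical(d(record), d(anon)), logical(1))
  out <- mean(same)
  attr(out, "per_decision") <- same
  out
}

#' Width-based information loss
#'
#' For interval-generalized (e.g. k-anonymized) data, the information loss
#' is the mean width of the anonymized per-sample intervals relative to the
#' overall domain width. Raw (zero-width) data scores exactly 0; fully
#' generalized data scores 1.
#'
#' @param widths per-sample interval widths in value units (0 for raw
#'   samples).
#' @param domain_width overall value-domain width (> 0).
#' @return fraction in `[0, 1]`.
#' @export
information_loss_width <- function(widths, domain_width) {
  stopifnot(domain_width > 0, all(widths >= 0),
            all(widths <= domain_width))
  mean(widths) / domain_width
}
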