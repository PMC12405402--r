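#' Discrete Fréchet distance between two curves
#'
#' The "dog-leash" distance restricted to the curves' vertices: the minimum
#' over all monotone couplings of the two point sequences of the maximum
#' Euclidean point distance in the `(t, v)` plane, computed by the standard
#' dynamic program. It is symmetric, non-negative, and zero exactly for
#' identical point sequences.
#'
#' Because time (seconds) and value (e.g. mV) carry different units,
#' `standardize = TRUE` rescales both axes by the pooled standard deviation
#' of the two curves before measuring; the constants used are attached as
#' the `"standardization"` attribute. The default is the raw Euclidean
#' metric, which keeps the distance interpretable in data units (a pure
#' value offset of `h` measures exactly `h`).
#'
#' @param c1,c2 curves: `tc_record`s, two-column matrices, data frames or
#'   `list(t, v)`.
#' @param standardize rescale axes by pooled per-axis standard deviation.
#' @return non-negative scalar distance.
#' @export
discrete_frechet <- function(c1, c2, standardize = FALSE) {
  a <- as_curve(c1); b <- as_curve(c2)
  if (!length(a$t) || !length(b$t)) stop("empty curve", call. = FALSE)
  consts <- NULL
  if (standardize) {
    st <- stats::sd(c(a$t, b$t)); sv <- stats::sd(c(a$v, b$v))
    if (!is.finite(st) || st == 0) st <- 1
    if (!is.finite(sv) || sv == 0) sv <- 1
    a$t <- a$t / st; b$t <- b$t / st
    a$v <- a$v / sv; b$v <- b$v / sv
    consts <- c(sd_t = st, sd_v = sv)
  }
  d <- .frechet_dp(a$t, a$v, b$t, b$v)
  if (!is.null(consts)) attr(d, "standardization") <- consts
  d
}

#' Baseline curve distances: Hausdorff and STED
#'
#' The Hausdorff distance treats both curves as point sets in the `(t, v)`
#' plane and reports how far one set must be thickened to contain the
#' other. The spatio-temporal Euclidean distance (STED) integrates the
#' pointwise value difference `|v1(t) - v2(t)|` (linear interpolation)
#' over the curves' common time support and normalizes by its length;
#' disjoint time supports make STED undefined.
#'
#' @param c1,c2 curves (see [discrete_frechet()] for accepted forms).
#' @return list with `hausdorff` and `sted`.
#' @export
baseline_distances <- function(c1, c2) {
  a <- as_curve(c1); b <- as_curve(c2)
  if (!length(a$t) || !length(b$t)) stop("empty curve", call. = FALSE)
  dmat <- sqrt(outer(a$t, b$t, "-")^2 + outer(a$v, b$v, "-")^2)
  hausdorff <- max(max(apply(dmat, 1, min)), max(apply(dmat, 2, min)))

  lo <- max(min(a$t), min(b$t)); hi <- min(max(a$t), max(b$t))
  if (lo >= hi)
    stop("STED undefined: curves have disjoint time support", call. = FALSE)
  knots <- sort(unique(c(lo, hi, a$t[a$t > lo & a$t < hi],
                         b$t[b$t > lo & b$t < hi])))
  v1 <- stats::approx(a$t, a$v, xout = knots, rule = 2)$y
  v2 <- stats::approx(b$t, b$v, xout = knots, rule = 2)$y
  d <- v1 - v2
  area <- 0
  for (k in seq_len(length(knots) - 1L)) {
    h <- knots[k + 1L] - knots[k]; d0 <- d[k]; d1 <- d[k + 1L]
    area <- area + if (d0 * d1 >= 0) (abs(d0) + abs(d1)) / 2 * h else {
      w <- d0 / (d0 - d1) # crossing point fraction
      (abs(d0) * w + abs(d1) * (1 - w)) / 2 * h
    }
  }
  list(hausdorff = hausdorff, sted = area / (hi - lo))
}

#' Unit-cost edit (Levenshtein) distance between symbol sequences
#'
#' Dynamic-programming Levenshtein distance with unit insert, delete and
#' substitute costs, on arbitrary symbol vectors (the event-signature
#' alphabet of the linkage attacks, not just characters).
#'
#' @param a,b character (or coercible) vectors of symbols.
#' @return integer count.
#' @export
edit_distance <- function(a, b) {
  a <- as.character(a); b <- as.character(b)
  n <- length(a); m <- length(b)
  if (n == 0) return(m)
  if (m == 0) return(n)
  prev <- 0:m
  for (i in seq_len(n)) {
    cur <- integer(m + 1L)
    cur[1] <- i
    for (j in seq_len(m)) {
      cur[j + 1L] <- min(prev[j + 1L] + 1L, cur[j] + 1L,
                         prev[j] + (a[i] != b[j]))
    }
    prev <- cur
  }
  as.integer(prev[m + 1L])
}
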