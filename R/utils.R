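#' @importFrom Rcpp sourceCpp
#' @useDynLib tcanon, .registration = TRUE
NULL

# derive a reproducible 32-bit child seed from a parent seed and an index
derive_seed <- function(seed, k = 1L) {
  as.integer((as.numeric(seed) * 48271 + 7919 * as.numeric(k)) %% 2147483647)
}

# sample from a Laplace(0, scale) distribution by inverse CDF
rlaplace <- function(n, scale) {
  if (scale == 0) return(rep(0, n))
  u <- stats::runif(n, -0.5, 0.5)
  -scale * sign(u) * log1p(-2 * abs(u))
}

# truncated Laplace via rejection sampling: the in-bound density stays
# proportional to the Laplace density (clamping would pile mass at bounds)
rlaplace_trunc <- function(n, scale, bound) {
  if (scale == 0 || bound == 0) return(rep(0, n))
  out <- rlaplace(n, scale)
  bad <- which(abs(out) > bound)
  guard <- 0L
  while (length(bad)) {
    out[bad] <- rlaplace(length(bad), scale)
    bad <- bad[abs(out[bad]) > bound]
    guard <- guard + 1L
    if (guard > 10000L) { # pathological scale >> bound: fall back to uniform
      out[bad] <- stats::runif(length(bad), -bound, bound)
      break
    }
  }
  out
}

# resample a curve onto an equidistant grid with the linear interpolate
resample_curve <- function(x, fs, t_range = NULL) {
  cv <- as_curve(x)
  if (is.null(t_range)) t_range <- range(cv$t)
  n <- max(2L, floor((t_range[2] - t_range[1]) * fs) + 1L)
  tt <- t_range[1] + (seq_len(n) - 1L) / fs
  tt[n] <- min(tt[n], t_range[2])
  vv <- stats::approx(cv$t, cv$v, xout = tt, method = "linear", rule = 2)$y
  list(t = tt, v = vv)
}

# coerce records / data.frames / matrices / lists to a bare curve
as_curve <- function(x) {
  if (inherits(x, "tc_sample_seq")) return(list(t = x$t, v = x$v))
  if (is.data.frame(x)) return(list(t = x[[1]], v = x[[2]]))
  if (is.matrix(x)) return(list(t = x[, 1], v = x[, 2]))
  if (is.list(x) && all(c("t", "v") %in% names(x)))
    return(list(t = as.numeric(x$t), v = as.numeric(x$v)))
  stop("cannot interpret object as a curve", call. = FALSE)
}
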