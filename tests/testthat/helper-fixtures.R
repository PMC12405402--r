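# Shared fixtures and independent oracles.

# tiny hand-built record
toy_record <- function(t = c(0, 1), v = c(1, 2), ...) {
  tc_record(t, v, channel = "ECG", unit = "mV", domain = c(-5, 5), ...)
}

# small default ECG used across tests (cached per session)
.fixture_env <- new.env()
fixture_ecg <- function(fs = 250, n_cycles = 5, seed = 11) {
  key <- paste(fs, n_cycles, seed, sep = "_")
  if (is.null(.fixture_env[[key]]))
    .fixture_env[[key]] <- generate_ecg(ecg_params(fs = fs),
                                        n_cycles = n_cycles, seed = seed)
  .fixture_env[[key]]
}

fixture_db <- function(seed = 42) {
  key <- paste0("db_", seed)
  if (is.null(.fixture_env[[key]]))
    .fixture_env[[key]] <- generate_database(n_persons = 5,
                                             records_per_person = 2,
                                             seed = seed)
  .fixture_env[[key]]
}

# Independent discrete-Frechet oracle: exhaustive recursion over all
# monotone couplings (no memoization), usable only for tiny curves.
frechet_brute <- function(c1, c2) {
  a <- if (is.list(c1)) c1 else list(t = c1[, 1], v = c1[, 2])
  b <- if (is.list(c2)) c2 else list(t = c2[, 1], v = c2[, 2])
  d <- function(i, j) sqrt((a$t[i] - b$t[j])^2 + (a$v[i] - b$v[j])^2)
  rec <- function(i, j) {
    here <- d(i, j)
    if (i == 1 && j == 1) return(here)
    prev <- c(if (i > 1) rec(i - 1, j),
              if (j > 1) rec(i, j - 1),
              if (i > 1 && j > 1) rec(i - 1, j - 1))
    max(min(prev), here)
  }
  rec(length(a$t), length(b$t))
}

# Independent Levenshtein oracle: naive ternary recursion, no memo.
lev_naive <- function(a, b) {
  if (!length(a)) return(length(b))
  if (!length(b)) return(length(a))
  min(lev_naive(a[-1], b) + 1L,
      lev_naive(a, b[-1]) + 1L,
      lev_naive(a[-1], b[-1]) + (a[1] != b[1]))
}

random_polyline <- function(n) {
  # anchored at t = 0 so any two polylines share time support
  list(t = cumsum(c(0, runif(n - 1, 0.1, 1))), v = rnorm(n))
}
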