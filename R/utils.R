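# Internal helpers: seeding, validation, small numerics.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Derive a reproducible substream seed from a master seed and a key
#'
#' All generators in the package draw from per-entity substreams so that, for
#' example, adding neurons to a simulated population does not perturb the
#' noise of existing ones. Substream seeds are a deterministic hash of the
#' master seed and a string key; the result is always in \code{[1, 2^31 - 2]}.
#'
#' @param seed integer master seed.
#' @param key character key naming the substream (e.g. \code{"traces/7"}).
#' @return a single integer seed.
#' @export
#' @examples
#' derive_seed(1, "licks") != derive_seed(1, "traces")
derive_seed <- function(seed, key) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.character(key))
  m <- 2147483647
  h <- 0
  for (ch in utf8ToInt(key)) h <- (h * 31 + ch) %% m
  s <- (abs(as.numeric(seed)) %% m)
  out <- (s * 48271 + h * 16807 + 12345) %% m
  out <- as.integer(out)
  if (out <= 0L) out <- 1L
  out
}

# Evaluate expr under a local RNG state seeded with `seed`.
with_substream <- function(seed, key, expr) {
  withr::with_seed(derive_seed(seed, key), expr)
}

assert_scalar_num <- function(x, name, positive = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stop(sprintf("`%s` must be a single finite number", name), call. = FALSE)
  if (positive && x <= 0)
    stop(sprintf("`%s` must be > 0", name), call. = FALSE)
  invisible(x)
}

# Sample indices covered by a half-open time window [start_s, end_s) on a
# regular grid where sample i (1-based) spans time [(i-1)/fs, i/fs).
window_index <- function(start_s, end_s, sample_rate, n_samples) {
  i0 <- floor(start_s * sample_rate) + 1L
  i1 <- ceiling(end_s * sample_rate)
  i0 <- max(1L, as.integer(i0))
  i1 <- min(as.integer(n_samples), as.integer(i1))
  if (i1 < i0) integer(0) else seq.int(i0, i1)
}

# Population (divide-by-n) standard deviation.
sd_pop <- function(x) {
  n <- length(x)
  if (n == 0L) return(NA_real_)
  mu <- mean(x)
  sqrt(sum((x - mu)^2) / n)
}

# Centered running mean with width w samples (odd); edges use shrunken window.
running_mean <- function(x, w) {
  w <- max(1L, as.integer(w))
  if (w %% 2L == 0L) w <- w + 1L
  n <- length(x)
  if (n == 0L || w == 1L) return(x)
  cs <- cumsum(c(0, x))
  half <- (w - 1L) %/% 2L
  lo <- pmax(1L, seq_len(n) - half)
  hi <- pmin(n, seq_len(n) + half)
  (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
}
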