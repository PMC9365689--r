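# Permutation tests and intra-class correlation across mice.

#' Permutation test for paired and unpaired comparisons
#'
#' Test statistic: the difference in sample means (unpaired) or the mean of
#' the paired differences. The null distribution is built by exhaustive
#' enumeration — all \code{2^n} sign flips (paired) or all
#' \code{choose(n + m, n)} group relabellings (unpaired) — whenever the
#' enumeration count is at most \code{exact_cap}; otherwise by \code{n_iter}
#' Monte-Carlo resamples, with the add-one (observed-statistic-included)
#' convention so p is never zero.
#'
#' @param x,y numeric samples. For \code{paired = TRUE} they must have equal
#'   length and the statistic is \code{mean(x - y)}.
#' @param paired logical, default FALSE.
#' @param sides 1 or 2. Two-sided tests compare \code{|T|}; one-sided tests
#'   use \code{alternative}.
#' @param alternative for \code{sides = 1}: \code{"greater"} (default) or
#'   \code{"less"}.
#' @param n_iter Monte-Carlo iterations (default 10000).
#' @param exact_cap maximum enumeration size for the exact path (default
#'   \code{2^20}).
#' @param seed integer seed for the Monte-Carlo path.
#' @return an object of class \code{perm_result}: \code{statistic},
#'   \code{p_value}, \code{exact}, \code{n_iterations}, \code{sides},
#'   \code{paired}, \code{seed}.
#' @export
#' @examples
#' permutation_test(c(2, 3, 4), c(1, 2, 3), paired = TRUE)  # exact, p = 0.25
permutation_test <- function(x, y, paired = FALSE, sides = 2,
                             alternative = c("greater", "less"),
                             n_iter = 10000, exact_cap = 2^20, seed = 1L) {
  alternative <- match.arg(alternative)
  stopifnot(sides %in% c(1, 2), length(x) >= 2, length(y) >= 2)
  eps <- 1e-12
  flip <- sides == 1 && alternative == "less"

  if (paired) {
    if (length(x) != length(y)) stop("paired samples must have equal length")
    d <- x - y
    if (flip) d <- -d
    t_obs <- mean(d)
    n <- length(d)
    if (all(d == 0)) {
      warning("all paired differences are zero; p = 1")
      return(perm_result(0, 1, TRUE, 2^n, sides, paired, seed))
    }
    if (2^n <= exact_cap) {
      # null statistics via subset sums: T = (2 * sum(subset) - sum(d)) / n
      ss <- 0
      for (v in d) ss <- c(ss, ss + v)
      t_null <- (2 * ss - sum(d)) / n
      p <- exact_p(t_null, t_obs, sides, eps)
      return(perm_result(signed(t_obs, flip), p, TRUE, 2^n, sides, paired,
                         seed))
    }
    t_null <- with_substream(seed, "perm-paired",
      vapply(seq_len(n_iter), function(i) {
        s <- sample(c(-1, 1), n, replace = TRUE)
        mean(s * d)
      }, numeric(1)))
    p <- mc_p(t_null, t_obs, sides, eps, n_iter)
    return(perm_result(signed(t_obs, flip), p, FALSE, n_iter, sides, paired,
                       seed))
  }

  if (flip) { tmp <- x; x <- y; y <- tmp }
  t_obs <- mean(x) - mean(y)
  pool <- c(x, y)
  n <- length(x); m <- length(y); N <- n + m
  if (all(pool == pool[1])) {
    warning("all values identical; p = 1")
    return(perm_result(0, 1, TRUE, choose(N, n), sides, paired, seed))
  }
  if (choose(N, n) <= exact_cap) {
    idx <- combn(N, n)
    tot <- sum(pool)
    sx <- colSums(matrix(pool[idx], nrow = n))
    t_null <- sx / n - (tot - sx) / m
    p <- exact_p(t_null, t_obs, sides, eps)
    return(perm_result(signed(t_obs, flip), p, TRUE, choose(N, n), sides,
                       paired, seed))
  }
  t_null <- with_substream(seed, "perm-unpaired",
    vapply(seq_len(n_iter), function(i) {
      sh <- sample.int(N)
      mean(pool[sh[seq_len(n)]]) - mean(pool[sh[(n + 1):N]])
    }, numeric(1)))
  p <- mc_p(t_null, t_obs, sides, eps, n_iter)
  perm_result(signed(t_obs, flip), p, FALSE, n_iter, sides, paired, seed)
}

signed <- function(t, flip) if (flip) -t else t

exact_p <- function(t_null, t_obs, sides, eps) {
  if (sides == 2) mean(abs(t_null) >= abs(t_obs) - eps)
  else mean(t_null >= t_obs - eps)
}

mc_p <- function(t_null, t_obs, sides, eps, n_iter) {
  k <- if (sides == 2) sum(abs(t_null) >= abs(t_obs) - eps)
       else sum(t_null >= t_obs - eps)
  (1 + k) / (n_iter + 1)
}

perm_result <- function(statistic, p, exact, iters, sides, paired, seed) {
  structure(list(statistic = statistic, p_value = p, exact = exact,
                 n_iterations = iters, sides = sides, paired = paired,
                 seed = seed),
            class = "perm_result")
}

#' @export
print.perm_result <- function(x, ...) {
  cat(sprintf("<perm_result> %s %s-sided: T = %.4g, p = %.4g (%s, %d)\n",
              if (x$paired) "paired" else "unpaired",
              if (x$sides == 2) "two" else "one",
              x$statistic, x$p_value,
              if (x$exact) "exact" else "Monte-Carlo", x$n_iterations))
  invisible(x)
}

#' Intra-class correlation across mice
#'
#' One-way random-effects variance decomposition (ANOVA method of moments):
#' the ICC is the between-mouse variance divided by the total variance, used
#' to check that a population effect is not driven by a single animal. A
#' negative between-mouse variance estimate is clipped to zero (the pre-clip
#' value is reported in the diagnostics).
#'
#' @param values numeric vector of per-neuron (or per-trial) measurements.
#' @param mouse_ids grouping vector of the same length; at least 2 mice.
#' @return an object of class \code{icc_result}: \code{icc},
#'   \code{variance_between}, \code{variance_within},
#'   \code{variance_between_raw}, \code{n_groups}.
#' @export
icc_between_mice <- function(values, mouse_ids) {
  stopifnot(length(values) == length(mouse_ids))
  ok <- is.finite(values)
  values <- values[ok]; mouse_ids <- as.character(mouse_ids)[ok]
  groups <- split(values, mouse_ids)
  k <- length(groups)
  if (k < 2) stop("ICC is undefined with a single mouse")
  ni <- lengths(groups)
  N <- sum(ni)
  grand <- mean(values)
  means <- vapply(groups, mean, numeric(1))
  ssb <- sum(ni * (means - grand)^2)
  ssw <- sum(vapply(groups, function(g) sum((g - mean(g))^2), numeric(1)))
  msb <- ssb / (k - 1)
  msw <- if (N - k > 0) ssw / (N - k) else 0
  n0 <- (N - sum(ni^2) / N) / (k - 1)
  vb_raw <- (msb - msw) / n0
  vb <- max(vb_raw, 0)
  icc <- if (vb + msw > 0) vb / (vb + msw) else 0
  structure(list(icc = icc, variance_between = vb, variance_within = msw,
                 variance_between_raw = vb_raw, n_groups = k),
            class = "icc_result")
}

#' @export
print.icc_result <- function(x, ...) {
  cat(sprintf("<icc_result> ICC = %.4f (between %.4g, within %.4g, %d mice)\n",
              x$icc, x$variance_between, x$variance_within, x$n_groups))
  invisible(x)
}
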