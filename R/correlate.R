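# Cross-condition correlation of matched neuron responses, and cross-session
# neuron matching by centroid assignment.

#' Correlate matched per-neuron responses across two conditions
#'
#' Ordinary least-squares regression and Pearson correlation of matched
#' per-neuron responses in two conditions, with a permutation test on the
#' pairing: condition-B responses are permuted across neurons and the
#' correlation recomputed. The p-value is exact (all \code{n!} pairings) when
#' feasible, otherwise Monte-Carlo with the add-one convention.
#'
#' @param resp_a,resp_b numeric vectors of matched per-neuron responses,
#'   \code{n >= 3}.
#' @param sides 1 or 2 (default 2).
#' @param n_iter Monte-Carlo iterations when exact enumeration is infeasible
#'   (default 10000).
#' @param exact_cap enumerate all pairings when \code{n! <= exact_cap}
#'   (default \code{2^20}).
#' @param conf_level confidence level of the regression band (default 0.95).
#' @param seed integer seed for the Monte-Carlo path.
#' @return list: \code{slope}, \code{intercept}, \code{r}, \code{p_value},
#'   \code{exact}, \code{n_iterations}, \code{sides}, and \code{ci_band}
#'   (data.frame \code{x}, \code{fit}, \code{lower}, \code{upper} at the
#'   sorted \code{resp_a} values).
#' @export
cross_condition_correlation <- function(resp_a, resp_b, sides = 2,
                                        n_iter = 10000, exact_cap = 2^20,
                                        conf_level = 0.95, seed = 1L) {
  stopifnot(length(resp_a) == length(resp_b))
  n <- length(resp_a)
  if (n < 3) stop("need at least 3 matched neurons")
  if (sd_pop(resp_a) == 0 || sd_pop(resp_b) == 0)
    stop("correlation undefined: zero variance in one condition")
  r_obs <- cor(resp_a, resp_b)
  fit <- lm(resp_b ~ resp_a)
  xs <- sort(resp_a)
  pred <- predict(fit, newdata = data.frame(resp_a = xs),
                  interval = "confidence", level = conf_level)

  eps <- 1e-12
  extreme <- function(r) if (sides == 2) abs(r) >= abs(r_obs) - eps
                         else r >= r_obs - eps
  if (factorial(n) <= exact_cap) {
    perms <- permutations_all(n)
    rs <- apply(perms, 1, function(p) cor(resp_a, resp_b[p]))
    p_val <- sum(extreme(rs)) / length(rs)
    exact <- TRUE; iters <- nrow(perms)
  } else {
    rs <- with_substream(seed, "xcorr-perm",
      vapply(seq_len(n_iter),
             function(i) cor(resp_a, resp_b[sample.int(n)]), numeric(1)))
    p_val <- (1 + sum(extreme(rs))) / (n_iter + 1)
    exact <- FALSE; iters <- n_iter
  }
  list(slope = unname(coef(fit)[2]), intercept = unname(coef(fit)[1]),
       r = r_obs, p_value = p_val, exact = exact, n_iterations = iters,
       sides = sides,
       ci_band = data.frame(x = xs, fit = pred[, "fit"],
                            lower = pred[, "lwr"], upper = pred[, "upr"]))
}

# All permutations of 1..n as an n! x n matrix (recursive; n <= 9 intended).
permutations_all <- function(n) {
  if (n == 1) return(matrix(1L, 1, 1))
  sub <- permutations_all(n - 1L)
  out <- matrix(0L, n * nrow(sub), n)
  row <- 1L
  for (k in seq_len(n)) {
    rest <- setdiff(seq_len(n), k)
    out[row:(row + nrow(sub) - 1L), ] <- cbind(k, matrix(rest[sub],
                                                         nrow(sub)))
    row <- row + nrow(sub)
  }
  out
}

#' Match neurons across sessions by centroid position
#'
#' One-to-one assignment of session-A neurons to session-B neurons minimizing
#' the total centroid distance, restricted to pairs within \code{max_dist}
#' (others are never matched). Uses the Hungarian algorithm; unmatched neurons
#' on either side are listed. This is a reconstruction of manual cross-session
#' cell alignment and the output is intended for manual verification.
#'
#' @param centroids_a,centroids_b numeric matrices (n x 2) of positions in a
#'   common registered coordinate frame (micrometres).
#' @param max_dist maximum match distance, micrometres (default 15, about one
#'   soma diameter).
#' @return list: \code{matches} data.frame (\code{index_a}, \code{index_b},
#'   \code{dist}), \code{unmatched_a}, \code{unmatched_b},
#'   \code{total_dist}.
#' @export
match_neurons <- function(centroids_a, centroids_b, max_dist = 15) {
  a <- as.matrix(centroids_a); b <- as.matrix(centroids_b)
  stopifnot(ncol(a) == 2, ncol(b) == 2)
  na <- nrow(a); nb <- nrow(b)
  if (na == 0 || nb == 0)
    return(list(matches = data.frame(index_a = integer(0),
                                     index_b = integer(0),
                                     dist = numeric(0)),
                unmatched_a = seq_len(na), unmatched_b = seq_len(nb),
                total_dist = 0))
  d <- sqrt(outer(a[, 1], b[, 1], "-")^2 + outer(a[, 2], b[, 2], "-")^2)
  big <- max_dist + max(d[d <= max_dist], 0) * (na + nb) + 1
  cost <- ifelse(d <= max_dist, d, big)
  assign <- hungarian(cost)
  keep <- !is.na(assign) & d[cbind(seq_len(na), assign)] <= max_dist
  matches <- data.frame(index_a = which(keep), index_b = assign[keep],
                        dist = d[cbind(which(keep), assign[keep])])
  matches <- matches[order(matches$index_a), , drop = FALSE]
  rownames(matches) <- NULL
  list(matches = matches,
       unmatched_a = setdiff(seq_len(na), matches$index_a),
       unmatched_b = setdiff(seq_len(nb), matches$index_b),
       total_dist = sum(matches$dist))
}

# Hungarian algorithm (shortest augmenting path with potentials) for an
# n x m cost matrix, n <= m handled by transposing internally.
# Returns, for each row, the assigned column (every row gets one when
# n <= m; rows of the larger side may be NA).
hungarian <- function(cost) {
  n <- nrow(cost); m <- ncol(cost)
  if (n > m) {
    inv <- hungarian(t(cost))
    out <- rep(NA_integer_, n)
    out[inv[!is.na(inv)]] <- which(!is.na(inv))
    return(out)
  }
  INF <- .Machine$double.xmax / 4
  u <- numeric(n + 1); v <- numeric(m + 1)
  p <- integer(m + 1)   # p[j]: row matched to column j (0 = none); p[m+1] aux
  way <- integer(m + 1)
  for (i in seq_len(n)) {
    p[m + 1] <- i
    j0 <- m + 1L        # virtual column
    minv <- rep(INF, m + 1)
    used <- rep(FALSE, m + 1)
    repeat {
      used[j0] <- TRUE
      i0 <- p[j0]; delta <- INF; j1 <- 0L
      for (j in seq_len(m)) {
        if (used[j]) next
        cur <- cost[i0, j] - u[i0] - v[j]
        if (cur < minv[j]) { minv[j] <- cur; way[j] <- j0 }
        if (minv[j] < delta) { delta <- minv[j]; j1 <- j }
      }
      for (j in seq_len(m + 1)) {
        if (used[j]) {
          if (p[j] > 0) u[p[j]] <- u[p[j]] + delta
          v[j] <- v[j] - delta
        } else {
          minv[j] <- minv[j] - delta
        }
      }
      j0 <- j1
      if (p[j0] == 0L) break
    }
    repeat {
      j1 <- way[j0]
      p[j0] <- p[j1]
      j0 <- j1
      if (j0 == m + 1L) break
    }
  }
  out <- rep(NA_integer_, n)
  for (j in seq_len(m)) if (p[j] > 0) out[p[j]] <- j
  out
}
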