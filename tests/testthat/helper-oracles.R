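# Independent brute-force oracles used across the suite. These deliberately
# re-derive each quantity by the most literal route possible.

# O(n^2) lick-bout segmentation: for every lick, grow the run forward while
# the next gap is <= max_gap; keep maximal runs spanning >= min_duration.
oracle_bouts <- function(times, min_duration = 10, max_gap = 2) {
  times <- sort(times)
  n <- length(times)
  rows <- list()
  i <- 1
  while (i <= n) {
    j <- i
    while (j < n && times[j + 1] - times[j] <= max_gap) j <- j + 1
    if (times[j] - times[i] >= min_duration)
      rows[[length(rows) + 1]] <- data.frame(start_s = times[i],
                                             end_s = times[j],
                                             n_licks = j - i + 1)
    i <- j + 1
  }
  if (!length(rows))
    return(data.frame(start_s = numeric(0), end_s = numeric(0),
                      n_licks = integer(0)))
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

# Exhaustive Otsu: scan every bin edge, maximizing between-class variance
# computed from first principles on bin midpoints.
oracle_otsu <- function(x, n_bins = 256) {
  x <- x[is.finite(x)]
  rng <- range(x)
  if (diff(rng) == 0) return(NA_real_)
  edges <- seq(rng[1], rng[2], length.out = n_bins + 1)
  bin <- pmin(pmax(findInterval(x, edges, rightmost.closed = TRUE), 1), n_bins)
  counts <- tabulate(bin, n_bins)
  mids <- (edges[-1] + edges[-(n_bins + 1)]) / 2
  best_bcv <- -Inf; best_thr <- NA_real_
  for (k in 1:(n_bins - 1)) {
    w0 <- sum(counts[1:k]); w1 <- sum(counts) - w0
    if (w0 == 0 || w1 == 0) next
    mu0 <- sum(counts[1:k] * mids[1:k]) / w0
    mu1 <- sum(counts[(k + 1):n_bins] * mids[(k + 1):n_bins]) / w1
    bcv <- w0 * w1 * (mu0 - mu1)^2
    if (bcv > best_bcv) { best_bcv <- bcv; best_thr <- edges[k + 1] }
  }
  best_thr
}

# Brute-force minimum-distance one-to-one matching over all permutations
# (n <= 7), pairs beyond max_dist forbidden.
oracle_match <- function(a, b, max_dist) {
  na <- nrow(a); nb <- nrow(b)
  d <- sqrt(outer(a[, 1], b[, 1], "-")^2 + outer(a[, 2], b[, 2], "-")^2)
  small <- min(na, nb)
  idx_small <- if (na <= nb) seq_len(na) else seq_len(nb)
  best <- list(cost = Inf, pairs = NULL)
  perms <- all_perms(max(na, nb))
  for (r in seq_len(nrow(perms))) {
    p <- perms[r, ]
    pairs <- if (na <= nb) cbind(seq_len(na), p[seq_len(na)])
             else cbind(p[seq_len(nb)], seq_len(nb))
    dist <- d[pairs]
    ok <- dist <= max_dist
    cost <- sum(dist[ok]) + sum(!ok) * 1e6  # minimize unmatched first
    if (cost < best$cost - 1e-12) best <- list(cost = cost,
                                               pairs = pairs[ok, , drop = FALSE])
  }
  best
}

all_perms <- function(n) {
  if (n == 1) return(matrix(1L, 1, 1))
  sub <- all_perms(n - 1L)
  do.call(rbind, lapply(seq_len(n), function(k) {
    rest <- setdiff(seq_len(n), k)
    cbind(k, matrix(rest[sub], nrow(sub)))
  }))
}

# Exact paired permutation p over all 2^n sign flips, by explicit bit loop.
oracle_paired_p <- function(d, sides = 2) {
  n <- length(d)
  t_obs <- mean(d)
  hits <- 0L
  for (mask in 0:(2^n - 1)) {
    s <- ifelse(bitwAnd(mask, 2^(0:(n - 1))) > 0, -1, 1)
    t_null <- mean(s * d)
    ex <- if (sides == 2) abs(t_null) >= abs(t_obs) - 1e-12
          else t_null >= t_obs - 1e-12
    if (ex) hits <- hits + 1L
  }
  hits / 2^n
}

# Exact unpaired permutation p over all group relabellings.
oracle_unpaired_p <- function(x, y, sides = 2) {
  pool <- c(x, y); n <- length(x); N <- length(pool)
  t_obs <- mean(x) - mean(y)
  cmb <- combn(N, n)
  hits <- 0L
  for (j in seq_len(ncol(cmb))) {
    xi <- cmb[, j]
    t_null <- mean(pool[xi]) - mean(pool[-xi])
    ex <- if (sides == 2) abs(t_null) >= abs(t_obs) - 1e-12
          else t_null >= t_obs - 1e-12
    if (ex) hits <- hits + 1L
  }
  hits / ncol(cmb)
}

# Textbook one-way ANOVA variance components by explicit sums of squares.
oracle_icc <- function(values, groups) {
  g <- split(values, groups)
  k <- length(g); ni <- lengths(g); N <- sum(ni)
  grand <- mean(values)
  ssb <- sum(ni * (vapply(g, mean, 0) - grand)^2)
  ssw <- sum(unlist(lapply(g, function(v) (v - mean(v))^2)))
  msb <- ssb / (k - 1); msw <- ssw / (N - k)
  n0 <- (N - sum(ni^2) / N) / (k - 1)
  vb <- max((msb - msw) / n0, 0)
  vb / (vb + msw)
}

# A small infusion-session fixture shared by several tests.
make_infusion_session <- function(n_neurons = 40, seed = 7,
                                  fractions = c(gi = 0.1,
                                                systemic_activated = 0.4,
                                                systemic_inhibited = 0.1),
                                  noise = list(), duration_min = 65) {
  design <- session_design("imaging", duration_min = duration_min,
                           manipulation = "ig_infusion",
                           infusion_rate_ul_min = 100,
                           infusion_volume_ul = 1200, seed = seed)
  events <- ingestphase:::session_events(design)
  truth <- gen_population(n_neurons, fractions, seed = seed)
  traces <- gen_traces(truth, events, design, noise, seed = seed)
  list(design = design, events = events, truth = truth, traces = traces)
}
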