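# Behavioural quantities: lick bouts, fluid preference, consumption,
# accelerometer movement segmentation.

#' Detect lick bouts
#'
#' A bout is any maximal run of licks in which no inter-lick interval exceeds
#' \code{max_gap} seconds and whose span (first to last lick) is at least
#' \code{min_duration} seconds. A gap of exactly \code{max_gap} stays within
#' the bout. The start of the first bout is the session's oral anchor and is
#' exposed as attribute \code{"first_bout_start"}.
#'
#' @param licks an \code{\link{event_log}} (lick events are used) or a numeric
#'   vector of lick times in seconds (sorted internally if needed).
#' @param min_duration minimum bout span, seconds (default 10).
#' @param max_gap maximum within-bout inter-lick interval, seconds (default 2).
#' @return a data.frame of class \code{bout_set} with \code{start_s},
#'   \code{end_s}, \code{n_licks}; empty if there are no bouts.
#' @export
#' @examples
#' detect_bouts(0:12)           # one 12-s bout of 13 licks
#' detect_bouts(0:8)            # span 8 s < 10 s: no bout
detect_bouts <- function(licks, min_duration = 10, max_gap = 2) {
  t <- if (inherits(licks, "event_log")) events_of(licks, "lick")
       else as.numeric(licks)
  t <- sort(t)
  if (!length(t)) {
    out <- data.frame(start_s = numeric(0), end_s = numeric(0),
                      n_licks = integer(0))
    class(out) <- c("bout_set", "data.frame")
    return(out)
  }
  run_id <- cumsum(c(1, as.integer(diff(t) > max_gap)))
  runs <- split(t, run_id)
  rows <- lapply(runs, function(r)
    data.frame(start_s = r[1], end_s = r[length(r)], n_licks = length(r)))
  out <- do.call(rbind, rows)
  out <- out[out$end_s - out$start_s >= min_duration, , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("bout_set", "data.frame")
  attr(out, "first_bout_start") <-
    if (nrow(out)) out$start_s[1] else NA_real_
  out
}

#' Fluid preference index
#'
#' The fraction of licks directed at the target solution:
#' \code{target / (target + other)}. For the two-bottle tests this is
#' conventionally the lime preference, \code{lime licks / total licks}.
#'
#' @param licks_target lick count for the target solution.
#' @param licks_other lick count for the other solution.
#' @return a fraction in \code{[0, 1]}.
#' @export
#' @examples
#' preference_index(75, 25)  # 0.75
preference_index <- function(licks_target, licks_other) {
  stopifnot(length(licks_target) == 1, length(licks_other) == 1,
            licks_target >= 0, licks_other >= 0)
  total <- licks_target + licks_other
  if (total == 0)
    stop("preference is undefined with zero total licks")
  licks_target / total
}

# Pool a two-day two-bottle test: lick-weighted preference for `flavour`.
pool_two_bottle <- function(test_df, flavour) {
  tgt <- sum(test_df$licks[test_df$flavour == flavour])
  oth <- sum(test_df$licks[test_df$flavour != flavour])
  preference_index(tgt, oth)
}

#' Per-mouse, per-day consumption summary of a training cohort
#'
#' Tabulates training-day licks and infused volume per solution. Under the
#' closed-loop rule each lick triggers a 1 ul infusion, so infused volume
#' equals lick count in microlitres; days with zero licks are reported as
#' zeros, not dropped.
#'
#' @param training a \code{\link{gen_training_cohort}} dataset.
#' @return data.frame: \code{mouse_id}, \code{day}, \code{flavour},
#'   \code{infused_solution}, \code{licks}, \code{infused_ul}.
#' @export
consumption_summary <- function(training) {
  stopifnot(inherits(training, "training_dataset"))
  rows <- lapply(training$mice, function(m) {
    data.frame(mouse_id = m$mouse_id,
               day = m$training$day,
               flavour = m$training$flavour,
               infused_solution = m$training$infused,
               licks = m$training$licks,
               infused_ul = m$training$licks * 1,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Otsu's threshold
#'
#' Histogram-based threshold maximizing the between-class variance, computed
#' over \code{n_bins} equal-width bins spanning the data range. Ties take the
#' lowest maximizing threshold. Thresholds are bin edges; values strictly
#' above the threshold fall in the upper class.
#'
#' @param x numeric vector.
#' @param n_bins number of histogram bins (default 256).
#' @return the threshold value, or \code{NA} if the data are degenerate
#'   (constant).
#' @export
otsu_threshold <- function(x, n_bins = 256) {
  x <- x[is.finite(x)]
  rng <- range(x)
  if (length(x) < 2 || diff(rng) == 0) return(NA_real_)
  edges <- seq(rng[1], rng[2], length.out = n_bins + 1)
  counts <- tabulate(pmin(pmax(findInterval(x, edges, rightmost.closed = TRUE),
                               1L), n_bins), nbins = n_bins)
  mids <- (edges[-1] + edges[-(n_bins + 1)]) / 2
  w <- cumsum(counts)
  m <- cumsum(counts * mids)
  n <- w[n_bins]; mt <- m[n_bins]
  # between-class variance for a split after bin k (k = 1..n_bins-1)
  k <- seq_len(n_bins - 1)
  w0 <- w[k]; w1 <- n - w0
  valid <- w0 > 0 & w1 > 0
  bcv <- rep(-Inf, n_bins - 1)
  bcv[valid] <- (mt * w0[valid] - m[k][valid] * n)^2 /
    (as.numeric(w0[valid]) * w1[valid])
  best <- which.max(bcv)
  edges[best + 1]
}

#' Segment an accelerometer stream into movement and rest
#'
#' Pipeline: rectified sum of the three axes, zero-phase third-order
#' Butterworth lowpass at 5 Hz (removing transients), then Otsu's threshold on
#' the filtered amplitude. Samples above the threshold are movement. A
#' degenerate (constant) filtered signal yields all-rest labels with a
#' warning.
#'
#' @param accel an \code{\link{accel_signal}}.
#' @param cutoff_hz lowpass cutoff, default 5.
#' @param n_bins Otsu histogram bins, default 256.
#' @return list: \code{moving} logical per sample, \code{threshold},
#'   \code{filtered} (the thresholded signal).
#' @export
movement_segments <- function(accel, cutoff_hz = 5, n_bins = 256) {
  stopifnot(inherits(accel, "accel_signal"))
  n <- ncol(accel$axes)
  if (n / accel$sample_rate < 2) stop("need at least 2 s of data")
  rect <- colSums(abs(accel$axes))
  filt <- lowpass_zerophase(rect, cutoff_hz, accel$sample_rate, order = 3)
  thr <- otsu_threshold(filt, n_bins)
  if (is.na(thr)) {
    warning("degenerate (constant) acceleration signal; labelling all rest")
    return(list(moving = rep(FALSE, n), threshold = NA_real_,
                filtered = filt))
  }
  list(moving = filt > thr, threshold = thr, filtered = filt)
}
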