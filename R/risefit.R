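# Sigmoidal onset-latency (t50) and persistence estimation.

#' Fit a sigmoidal rise to a responding neuron and estimate t50 and
#' persistence
#'
#' Fits a 4-parameter logistic \code{f(t) = floor + amplitude * plogis((t -
#' midpoint) / slope)} by least squares to the normalized trace over a
#' post-anchor window, with a multi-start grid over the midpoint (window
#' quartiles) and slope. The logistic models the rise, so the fit uses the
#' window only up to the smoothed peak of the response; including the later
#' return to baseline would bias the midpoint. The rise time t50 is the
#' fitted midpoint — the time
#' at which the response reaches 50\% of its peak change. Persistence is
#' measured on the smoothed trace as the time it stays at or above 50\% of its
#' peak change (from the upward half-peak crossing to the downward one).
#' Inhibited responses are fitted on the sign-flipped trace, so t50 is
#' symmetric between mirrored activated/inhibited pairs.
#'
#' @param z numeric vector, the neuron's normalized trace (z-units, baseline
#'   mean 0), full session.
#' @param sample_rate Hz.
#' @param anchor_s anchor time in seconds (e.g. infusion start); t50 and
#'   persistence are reported in minutes from this anchor.
#' @param window_s length-2 fitting window in seconds from session start;
#'   must span at least 4 minutes. Default: anchor to end of trace.
#' @param direction \code{"activated"} or \code{"inhibited"}.
#' @param slope_starts_min starting slopes for the multi-start grid (minutes).
#' @param smooth_s running-mean width for the persistence measurement,
#'   seconds (default 30).
#' @return an object of class \code{rise_fit}: \code{floor},
#'   \code{amplitude}, \code{midpoint_min}, \code{slope_min}, \code{t50_min},
#'   \code{persistence_min}, \code{r_squared}, \code{converged},
#'   \code{direction}. Non-convergent fits return \code{converged = FALSE}
#'   with \code{NA} estimates.
#' @export
fit_rise <- function(z, sample_rate, anchor_s = 0, window_s = NULL,
                     direction = c("activated", "inhibited"),
                     slope_starts_min = c(0.5, 2, 5), smooth_s = 30) {
  direction <- match.arg(direction)
  n <- length(z)
  if (is.null(window_s)) window_s <- c(anchor_s, n / sample_rate)
  if (diff(window_s) < 4 * 60) stop("fitting window must span >= 4 min")
  idx <- window_index(window_s[1], window_s[2], sample_rate, n)
  t_min <- ((idx - 1) / sample_rate - anchor_s) / 60
  y <- z[idx]
  if (direction == "inhibited") y <- -y

  # The logistic models the rise only; fit up to the (smoothed) peak so the
  # later return to baseline cannot bias the midpoint. Persistence is
  # measured on the full window below.
  sm <- running_mean(y, round(smooth_s * sample_rate))
  pk_i <- which.max(sm)
  fit_end <- max(pk_i, which(t_min - t_min[1] >= 4)[1])
  tf <- t_min[1:fit_end]
  yf <- y[1:fit_end]

  q <- quantile(tf, c(0.25, 0.5, 0.75))
  floor0 <- quantile(yf, 0.05)
  amp0 <- max(quantile(yf, 0.95) - floor0, 1e-6)
  best <- NULL
  for (m0 in q) for (k0 in slope_starts_min) {
    fit <- tryCatch(
      minpack.lm::nlsLM(
        yf ~ b + A * stats::plogis((tf - m) / k),
        start = list(b = floor0, A = amp0, m = unname(m0), k = k0),
        lower = c(b = -Inf, A = 0, m = min(tf), k = 1e-3),
        upper = c(b = Inf, A = Inf, m = max(tf), k = diff(range(tf))),
        control = minpack.lm::nls.lm.control(maxiter = 300)),
      error = function(e) NULL)
    if (is.null(fit)) next
    rss <- sum(stats::resid(fit)^2)
    if (is.null(best) || rss < best$rss)
      best <- c(as.list(coef(fit)), list(rss = rss))
  }
  if (is.null(best)) {
    return(structure(list(floor = NA_real_, amplitude = NA_real_,
                          midpoint_min = NA_real_, slope_min = NA_real_,
                          t50_min = NA_real_, persistence_min = NA_real_,
                          r_squared = NA_real_, converged = FALSE,
                          direction = direction),
                     class = "rise_fit"))
  }
  tss <- sum((yf - mean(yf))^2)
  r2 <- if (tss > 0) 1 - best$rss / tss else NA_real_
  t50 <- unname(best$m)
  in_window <- t50 >= min(t_min) && t50 <= max(t_min)

  # persistence on the smoothed trace: contiguous time at/above half-peak
  half <- best$b + 0.5 * (sm[pk_i] - best$b)
  above <- sm >= half
  up <- pk_i; while (up > 1 && above[up - 1]) up <- up - 1
  dn <- pk_i; while (dn < length(sm) && above[dn + 1]) dn <- dn + 1
  persistence <- t_min[dn] - t_min[up]

  structure(list(floor = unname(best$b), amplitude = unname(best$A),
                 midpoint_min = t50, slope_min = unname(best$k),
                 t50_min = if (in_window) t50 else NA_real_,
                 persistence_min = persistence,
                 r_squared = r2, converged = in_window,
                 direction = direction),
            class = "rise_fit")
}

#' @export
print.rise_fit <- function(x, ...) {
  if (!x$converged) {
    cat("<rise_fit> non-convergent\n")
  } else {
    cat(sprintf(
      "<rise_fit> %s: t50 = %.2f min, persistence = %.2f min (R^2 = %.3f)\n",
      x$direction, x$t50_min, x$persistence_min, x$r_squared))
  }
  invisible(x)
}
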