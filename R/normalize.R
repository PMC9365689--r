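# Normalization: baseline z-scoring, bleach screening, slow baseline
# fluorescence, isosbestic dF/F0, anti-aliased downsampling.

#' Baseline z-score normalization of calcium traces
#'
#' Normalizes every trace as \code{z = (raw - mu) / sigma}, where \code{mu}
#' and \code{sigma} are that neuron's mean and (population) standard deviation
#' over the baseline window — by default the first 10 minutes of the
#' recording, before any manipulation. Neurons whose baseline is exactly
#' constant are normalized to \code{z == 0}; neurons with zero baseline
#' variance but non-constant traces are excluded as degenerate.
#'
#' @param traces a \code{\link{trace_matrix}}.
#' @param baseline_window length-2 numeric, seconds \code{c(start, end)};
#'   default \code{c(0, 600)}.
#' @return a \code{z_trace_matrix}: list with \code{values} (z-units),
#'   \code{sample_rate}, \code{neuron_ids}, \code{baseline_window},
#'   \code{mu}, \code{sigma}, and \code{excluded} (a data.frame of degenerate
#'   neurons with reasons).
#' @export
zscore_traces <- function(traces, baseline_window = c(0, 600)) {
  stopifnot(inherits(traces, "trace_matrix"))
  n_samp <- ncol(traces$values)
  idx <- window_index(baseline_window[1], baseline_window[2],
                      traces$sample_rate, n_samp)
  if (length(idx) < 2 || baseline_window[1] < 0 ||
      baseline_window[2] > n_samp / traces$sample_rate + 1e-9)
    stop("baseline window must lie inside the recording")
  mu <- rowMeans(traces$values[, idx, drop = FALSE])
  sigma <- apply(traces$values[, idx, drop = FALSE], 1, sd_pop)

  keep <- rep(TRUE, length(mu))
  zero_sd <- sigma <= 0
  constant <- zero_sd & apply(traces$values, 1, function(r) all(r == r[1]))
  degenerate <- zero_sd & !constant
  keep[degenerate] <- FALSE
  z <- (traces$values - mu) / ifelse(zero_sd, 1, sigma)
  z[constant, ] <- 0

  excluded <- data.frame(
    neuron_id = traces$neuron_ids[degenerate],
    reason = rep("zero baseline sd with non-constant trace",
                 sum(degenerate)),
    stringsAsFactors = FALSE)
  structure(
    list(values = z[keep, , drop = FALSE],
         sample_rate = traces$sample_rate,
         neuron_ids = traces$neuron_ids[keep],
         baseline_window = baseline_window,
         mu = mu[keep], sigma = sigma[keep],
         excluded = excluded),
    class = "z_trace_matrix")
}

#' @export
print.z_trace_matrix <- function(x, ...) {
  cat(sprintf("<z_trace_matrix> %d neurons x %d samples @ %.4g Hz, baseline [%g, %g] s\n",
              nrow(x$values), ncol(x$values), x$sample_rate,
              x$baseline_window[1], x$baseline_window[2]))
  invisible(x)
}

#' Screen out neurons with baseline bleaching artifacts
#'
#' Fits \code{A * exp(-t / tau) + c} to each neuron's baseline segment and
#' excludes neurons for which the fit explains most of the baseline variance
#' and the fitted amplitude is large relative to the baseline fluctuation —
#' the signature of a photobleaching transient rather than neural activity.
#'
#' @param traces a \code{\link{trace_matrix}}.
#' @param baseline_window length-2 numeric, seconds; default \code{c(0, 600)}.
#' @param criteria list: \code{r2_min} minimum fraction of baseline variance
#'   explained by the exponential (default 0.8), \code{amp_min_sd} minimum
#'   fitted amplitude in units of the baseline standard deviation (default 2),
#'   and \code{fit_rate_hz} the rate the baseline is block-averaged to before
#'   fitting (default 1; bleaching is a slow signal, so fitting at 1 Hz loses
#'   nothing while keeping the exponential fits cheap).
#' @return list with \code{kept} and \code{excluded} neuron id vectors and
#'   \code{diagnostics}, a per-neuron data.frame of fitted \code{A},
#'   \code{tau_s}, \code{c}, \code{r_squared}, \code{amp_sd} and the decision.
#' @export
screen_bleaching <- function(traces, baseline_window = c(0, 600),
                             criteria = list()) {
  stopifnot(inherits(traces, "trace_matrix"))
  cr <- utils::modifyList(list(r2_min = 0.8, amp_min_sd = 2, fit_rate_hz = 1),
                          criteria)
  idx <- window_index(baseline_window[1], baseline_window[2],
                      traces$sample_rate, ncol(traces$values))
  if (length(idx) < 3) stop("baseline must contain at least 3 samples")
  fit_rate <- min(cr$fit_rate_hz, traces$sample_rate)
  t_full <- (idx - 1) / traces$sample_rate

  rows <- lapply(seq_len(nrow(traces$values)), function(i) {
    y_full <- traces$values[i, idx]
    if (fit_rate < traces$sample_rate) {
      y <- downsample_series(y_full, fit_rate, traces$sample_rate)
      t_s <- t_full[1] + (seq_along(y) - 0.5) / fit_rate
    } else {
      y <- y_full; t_s <- t_full
    }
    s <- sd_pop(y)
    fit <- fit_exp_decay(t_s, y)
    if (is.null(fit))
      return(data.frame(neuron_id = traces$neuron_ids[i], A = NA, tau_s = NA,
                        c = NA, r_squared = NA, amp_sd = NA,
                        excluded = FALSE, stringsAsFactors = FALSE))
    amp_sd <- if (s > 0) abs(fit$A) / s else Inf
    excl <- is.finite(fit$r2) && fit$r2 >= cr$r2_min &&
      amp_sd >= cr$amp_min_sd && fit$A > 0
    data.frame(neuron_id = traces$neuron_ids[i], A = fit$A, tau_s = fit$tau,
               c = fit$c, r_squared = fit$r2, amp_sd = amp_sd,
               excluded = excl, stringsAsFactors = FALSE)
  })
  diag <- do.call(rbind, rows)
  list(kept = diag$neuron_id[!diag$excluded],
       excluded = diag$neuron_id[diag$excluded],
       diagnostics = diag)
}

# Least-squares fit of A*exp(-t/tau) + c; NULL if it cannot be fit.
fit_exp_decay <- function(t_s, y) {
  if (length(y) < 3 || sd_pop(y) == 0) return(NULL)
  span <- max(t_s) - min(t_s)
  starts <- expand.grid(A = c(y[1] - y[length(y)], 2 * sd_pop(y)),
                        tau = span * c(0.1, 0.3, 0.8))
  best <- NULL
  for (j in seq_len(nrow(starts))) {
    fit <- tryCatch(
      minpack.lm::nlsLM(
        y ~ A * exp(-(t_s - min(t_s)) / tau) + c0,
        start = list(A = starts$A[j], tau = max(starts$tau[j], 1e-3),
                     c0 = y[length(y)]),
        lower = c(A = -Inf, tau = 1e-3, c0 = -Inf),
        control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) NULL)
    if (is.null(fit)) next
    rss <- sum(stats::resid(fit)^2)
    if (is.null(best) || rss < best$rss)
      best <- c(as.list(coef(fit)), list(rss = rss))
  }
  if (is.null(best)) return(NULL)
  tss <- sum((y - mean(y))^2)
  list(A = best$A, tau = best$tau, c = best$c0,
       r2 = if (tss > 0) 1 - best$rss / tss else NA_real_)
}

#' Extract the slow baseline-fluorescence component
#'
#' Applies a zero-phase (forward-backward) Butterworth lowpass with cutoff
#' 1/60 Hz to each trace, removing all changes faster than one minute while
#' preserving DC exactly. Edges are handled by reflection padding.
#'
#' @param traces a \code{\link{trace_matrix}} (or a numeric vector with
#'   \code{sample_rate} supplied).
#' @param cutoff_hz lowpass cutoff, default \code{1/60}.
#' @param order Butterworth order per pass, default 2.
#' @param sample_rate required if \code{traces} is a bare numeric vector.
#' @return same shape as the input: a \code{trace_matrix} or numeric vector
#'   of the slow component.
#' @export
baseline_fluorescence <- function(traces, cutoff_hz = 1 / 60, order = 2,
                                  sample_rate = NULL) {
  if (inherits(traces, "trace_matrix")) {
    fs <- traces$sample_rate
    if (ncol(traces$values) / fs < 120)
      stop("recording must be at least 2 min long")
    out <- t(apply(traces$values, 1, lowpass_zerophase,
                   cutoff_hz = cutoff_hz, fs = fs, order = order))
    return(trace_matrix(out, fs, traces$neuron_ids))
  }
  if (is.null(sample_rate)) stop("supply `sample_rate` for a bare vector")
  if (length(traces) / sample_rate < 120)
    stop("recording must be at least 2 min long")
  lowpass_zerophase(traces, cutoff_hz, sample_rate, order)
}

# Zero-phase Butterworth lowpass with reflection padding.
lowpass_zerophase <- function(x, cutoff_hz, fs, order = 2) {
  wn <- cutoff_hz / (fs / 2)
  if (wn >= 1) return(x)
  bf <- signal::butter(order, wn, type = "low")
  npad <- min(length(x) - 1L, max(3L * 10L, ceiling(3 * fs / cutoff_hz)))
  pre <- 2 * x[1] - x[seq(npad + 1L, 2L)]
  post <- 2 * x[length(x)] - x[seq(length(x) - 1L, length(x) - npad)]
  y <- signal::filtfilt(bf, c(pre, x, post))
  y[(npad + 1L):(npad + length(x))]
}

#' Isosbestic-regression dF/F0 for dual-channel photometry
#'
#' Fits \code{F_signal ~ a * F_reference + b} by ordinary least squares on the
#' baseline window only, predicts \code{F0(t) = a * F_reference(t) + b} over
#' the whole session, and returns \code{dF/F0 = (F - F0) / F0}. Because the
#' 405-nm reference is insensitive to the sensor's ligand, F0 captures motion
#' and bleaching artifacts common to both channels.
#'
#' @param phot a \code{\link{photometry_signal}}.
#' @param baseline_window length-2 numeric, seconds; default \code{c(0, 600)}.
#' @return a \code{dff_trace}: list with \code{values} (dF/F0; samples where
#'   \code{F0 <= 0} are \code{NA} and counted in \code{n_masked}),
#'   \code{sample_rate}, \code{coefficients} (slope, intercept), and
#'   \code{baseline_window}.
#' @export
dff_isosbestic <- function(phot, baseline_window = c(0, 600)) {
  stopifnot(inherits(phot, "photometry_signal"))
  idx <- window_index(baseline_window[1], baseline_window[2],
                      phot$sample_rate, length(phot$signal))
  if (length(idx) < 3) stop("baseline window must contain >= 3 samples")
  ref_b <- phot$reference[idx]
  if (sd_pop(ref_b) == 0)
    stop("reference channel is constant over the baseline; cannot regress")
  fit <- lm(phot$signal[idx] ~ ref_b)
  a <- unname(coef(fit)[2]); b <- unname(coef(fit)[1])
  f0 <- a * phot$reference + b
  bad <- f0 <= 0
  dff <- (phot$signal - f0) / f0
  dff[bad] <- NA_real_
  if (any(bad))
    warning(sum(bad), " samples masked where predicted F0 <= 0")
  structure(list(values = dff, sample_rate = phot$sample_rate,
                 coefficients = c(slope = a, intercept = b),
                 baseline_window = baseline_window,
                 n_masked = sum(bad)),
            class = "dff_trace")
}

#' @export
print.dff_trace <- function(x, ...) {
  cat(sprintf("<dff_trace> %d samples @ %.4g Hz; F0 = %.3g * ref + %.3g (%d masked)\n",
              length(x$values), x$sample_rate, x$coefficients["slope"],
              x$coefficients["intercept"], x$n_masked))
  invisible(x)
}

#' Anti-aliased (block-average) downsampling
#'
#' Averages all native samples whose bin index \code{floor(t * target_rate)}
#' matches each output sample, so the output is an exact windowed mean and its
#' length is \code{floor(n * target_rate / native_rate)}. For an integer rate
#' ratio this reduces to non-overlapping block means.
#'
#' @param x numeric vector, or a \code{\link{trace_matrix}}.
#' @param native_rate Hz of \code{x} (taken from the object if a
#'   \code{trace_matrix}).
#' @param target_rate Hz, must be \code{<= native_rate}.
#' @return same type as the input, at \code{target_rate}.
#' @export
downsample_series <- function(x, target_rate, native_rate = NULL) {
  if (inherits(x, "trace_matrix")) {
    out <- t(apply(x$values, 1, downsample_series,
                   target_rate = target_rate, native_rate = x$sample_rate))
    return(trace_matrix(out, target_rate, x$neuron_ids))
  }
  if (inherits(x, "dff_trace")) {
    v <- downsample_series(x$values, target_rate, x$sample_rate)
    out <- x; out$values <- v; out$sample_rate <- target_rate
    return(out)
  }
  if (is.null(native_rate)) stop("supply `native_rate` for a bare vector")
  if (target_rate > native_rate) stop("target_rate must be <= native_rate")
  n_out <- floor(length(x) * target_rate / native_rate)
  if (n_out == 0) return(numeric(0))
  t_s <- (seq_along(x) - 1) / native_rate
  bin <- floor(t_s * target_rate)
  keep <- bin < n_out
  as.numeric(tapply(x[keep], bin[keep], mean))
}
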