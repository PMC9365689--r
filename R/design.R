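# Session designs and the core data containers.

MANIPULATIONS <- c("drinking", "ig_infusion", "ip_injection",
                   "closed_loop_training")
MODALITIES <- c("imaging", "photometry")
EVENT_KINDS <- c("lick", "infusion_start", "infusion_stop", "injection",
                 "access_start", "access_stop")
ARCHETYPES <- c("oral", "gi", "systemic_activated", "systemic_inhibited",
                "none")

#' Describe a recording session to be simulated or analysed
#'
#' A session design fixes the recording modality, duration, sampling and the
#' physiological manipulation. Imaging sessions default to 8 Hz (typical
#' miniscope frame rate); photometry sessions default to ~1017 Hz acquisition,
#' which downstream analysis downsamples to 4 Hz. The first
#' \code{baseline_min} minutes are the pre-manipulation baseline used for all
#' normalization.
#'
#' @param modality \code{"imaging"} or \code{"photometry"}.
#' @param duration_min session length, minutes.
#' @param manipulation one of \code{"drinking"}, \code{"ig_infusion"},
#'   \code{"ip_injection"}, \code{"closed_loop_training"}.
#' @param sample_rate Hz; defaults to 8 (imaging) or 1017.25 (photometry).
#' @param baseline_min baseline period at the start of the recording, minutes
#'   (default 10).
#' @param infusion_rate_ul_min intragastric infusion rate in ul/min (100 or
#'   200 in the experiments this emulates). Required for \code{ig_infusion},
#'   disallowed otherwise.
#' @param infusion_volume_ul total infused volume in ul (600 or 1200
#'   typically). Required for \code{ig_infusion}, disallowed otherwise.
#' @param seed integer seed recorded with the design; generators combine it
#'   with their own \code{seed} argument via \code{\link{derive_seed}}.
#' @return an object of class \code{session_design}.
#' @export
#' @examples
#' session_design("imaging", duration_min = 65, manipulation = "ig_infusion",
#'                infusion_rate_ul_min = 100, infusion_volume_ul = 1200)
session_design <- function(modality,
                           duration_min,
                           manipulation,
                           sample_rate = NULL,
                           baseline_min = 10,
                           infusion_rate_ul_min = NULL,
                           infusion_volume_ul = NULL,
                           seed = 1L) {
  modality <- match.arg(modality, MODALITIES)
  manipulation <- match.arg(manipulation, MANIPULATIONS)
  if (is.null(sample_rate))
    sample_rate <- if (modality == "imaging") 8 else 1017.25
  assert_scalar_num(duration_min, "duration_min", positive = TRUE)
  assert_scalar_num(sample_rate, "sample_rate", positive = TRUE)
  assert_scalar_num(baseline_min, "baseline_min")
  if (baseline_min < 0) stop("`baseline_min` must be >= 0")
  if (duration_min <= baseline_min)
    stop("`duration_min` must exceed `baseline_min`")
  if (manipulation == "ig_infusion") {
    if (is.null(infusion_rate_ul_min) || is.null(infusion_volume_ul))
      stop("ig_infusion designs require `infusion_rate_ul_min` and ",
           "`infusion_volume_ul`")
    assert_scalar_num(infusion_rate_ul_min, "infusion_rate_ul_min",
                      positive = TRUE)
    assert_scalar_num(infusion_volume_ul, "infusion_volume_ul",
                      positive = TRUE)
  } else if (!is.null(infusion_rate_ul_min) || !is.null(infusion_volume_ul)) {
    stop("infusion fields are only meaningful for `ig_infusion` designs ",
         "(closed-loop training infuses 1 ul per lick)")
  }
  structure(
    list(modality = modality,
         duration_min = duration_min,
         manipulation = manipulation,
         sample_rate = sample_rate,
         baseline_min = baseline_min,
         infusion_rate_ul_min = infusion_rate_ul_min,
         infusion_volume_ul = infusion_volume_ul,
         seed = as.integer(seed)),
    class = "session_design")
}

#' @export
print.session_design <- function(x, ...) {
  cat(sprintf("<session_design> %s / %s, %.1f min @ %.4g Hz (baseline %.1f min)\n",
              x$modality, x$manipulation, x$duration_min, x$sample_rate,
              x$baseline_min))
  if (!is.null(x$infusion_volume_ul))
    cat(sprintf("  infusion: %.0f ul at %.0f ul/min\n",
                x$infusion_volume_ul, x$infusion_rate_ul_min))
  invisible(x)
}

#' Construct a typed behavioural event log
#'
#' @param time_s event times in seconds from recording start; must be
#'   non-decreasing (sorted internally with a stable order otherwise).
#' @param kind one of \code{"lick"}, \code{"infusion_start"},
#'   \code{"infusion_stop"}, \code{"injection"}, \code{"access_start"},
#'   \code{"access_stop"}.
#' @param solution optional solution label per event (e.g. \code{"water"},
#'   \code{"NaCl_600mM"}, \code{"grape"}).
#' @param volume_ul optional volume per event, microlitres.
#' @return a data.frame of class \code{event_log} with columns
#'   \code{time_s}, \code{kind}, \code{solution}, \code{volume_ul}.
#' @export
event_log <- function(time_s = numeric(0), kind = character(0),
                      solution = NA_character_, volume_ul = NA_real_) {
  stopifnot(length(time_s) == length(kind))
  if (length(kind)) kind <- match.arg(kind, EVENT_KINDS, several.ok = TRUE)
  df <- data.frame(time_s = as.numeric(time_s),
                   kind = as.character(kind),
                   solution = rep_len(as.character(solution),
                                      length(time_s)),
                   volume_ul = rep_len(as.numeric(volume_ul), length(time_s)),
                   stringsAsFactors = FALSE)
  df <- df[order(df$time_s), , drop = FALSE]
  rownames(df) <- NULL
  n_start <- sum(df$kind == "infusion_start")
  n_stop <- sum(df$kind == "infusion_stop")
  if (n_start != n_stop)
    stop("every infusion_start must have a matching infusion_stop")
  if (n_start > 0) {
    st <- df$time_s[df$kind == "infusion_start"]
    sp <- df$time_s[df$kind == "infusion_stop"]
    if (any(sp <= st))
      stop("each infusion_stop must follow its infusion_start")
  }
  class(df) <- c("event_log", "data.frame")
  df
}

# Combine event logs preserving the class.
bind_events <- function(...) {
  parts <- Filter(function(p) !is.null(p) && nrow(p) > 0, list(...))
  if (!length(parts)) return(event_log())
  df <- do.call(rbind, lapply(parts, as.data.frame))
  event_log(df$time_s, df$kind, df$solution, df$volume_ul)
}

events_of <- function(events, kind) events$time_s[events$kind == kind]

#' Construct a neurons-by-time fluorescence trace matrix
#'
#' @param values numeric matrix, neurons in rows, samples in columns.
#' @param sample_rate sampling rate, Hz.
#' @param neuron_ids unique identifiers, defaults to \code{"n1"..}.
#' @param spikes optional matrix of inferred event rates, same shape as
#'   \code{values} (stored, not analysed further here).
#' @return an object of class \code{trace_matrix}.
#' @export
trace_matrix <- function(values, sample_rate, neuron_ids = NULL,
                         spikes = NULL) {
  values <- as.matrix(values)
  if (!all(is.finite(values))) stop("trace values must be finite")
  assert_scalar_num(sample_rate, "sample_rate", positive = TRUE)
  if (is.null(neuron_ids)) neuron_ids <- paste0("n", seq_len(nrow(values)))
  if (anyDuplicated(neuron_ids)) stop("neuron_ids must be unique")
  if (!is.null(spikes)) {
    spikes <- as.matrix(spikes)
    stopifnot(identical(dim(spikes), dim(values)))
  }
  rownames(values) <- neuron_ids
  structure(list(values = values, sample_rate = sample_rate,
                 neuron_ids = as.character(neuron_ids), spikes = spikes),
            class = "trace_matrix")
}

#' @export
print.trace_matrix <- function(x, ...) {
  cat(sprintf("<trace_matrix> %d neurons x %d samples @ %.4g Hz (%.1f min)\n",
              nrow(x$values), ncol(x$values), x$sample_rate,
              ncol(x$values) / x$sample_rate / 60))
  invisible(x)
}

#' Construct a dual-channel photometry signal
#'
#' @param signal calcium/dopamine-sensitive channel (470 nm excitation).
#' @param reference isosbestic channel (405 nm excitation), same length.
#' @param sample_rate Hz.
#' @return an object of class \code{photometry_signal}.
#' @export
photometry_signal <- function(signal, reference, sample_rate) {
  signal <- as.numeric(signal); reference <- as.numeric(reference)
  if (length(signal) != length(reference))
    stop("signal and reference must have equal length")
  if (!all(is.finite(signal)) || !all(is.finite(reference)))
    stop("photometry channels must be finite")
  assert_scalar_num(sample_rate, "sample_rate", positive = TRUE)
  structure(list(signal = signal, reference = reference,
                 sample_rate = sample_rate),
            class = "photometry_signal")
}

#' Construct a 3-axis accelerometer signal
#'
#' @param axes numeric matrix with 3 rows (x, y, z) and one column per sample.
#' @param sample_rate Hz (50 in the hardware this emulates).
#' @return an object of class \code{accel_signal}.
#' @export
accel_signal <- function(axes, sample_rate = 50) {
  axes <- as.matrix(axes)
  if (nrow(axes) != 3L) stop("accelerometer data must have 3 axes (rows)")
  if (!all(is.finite(axes))) stop("acceleration values must be finite")
  assert_scalar_num(sample_rate, "sample_rate", positive = TRUE)
  structure(list(axes = axes, sample_rate = sample_rate),
            class = "accel_signal")
}
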