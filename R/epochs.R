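# Stage epochs, per-neuron response means, classification, population summary.

#' Define the ingestion-stage epochs for a session
#'
#' Builds the analysis windows for the oral, gastrointestinal and systemic
#' stages, anchored to behavioural events:
#' \itemize{
#'   \item oral: 30 s from the start of the first lick bout;
#'   \item gastrointestinal: first 12 min after intragastric infusion start;
#'   \item systemic: 12–32 min (imaging) or 12–50 min (photometry) after the
#'     anchor (infusion start, or the first lick bout for drinking sessions);
#'   \item ip_systemic: 0–30 min after intraperitoneal injection;
#'   \item baseline: the 10 min preceding the anchor (clipped at 0).
#' }
#' The \code{"legacy_end_anchored"} preset instead defines a single
#' \code{post_ingestion} window 0–20 min after the end of consumption or
#' infusion (with IP injections unchanged), matching the end-anchored
#' convention sometimes used before rise-time analysis motivated the
#' start-anchored windows.
#'
#' @param events an \code{\link{event_log}}.
#' @param modality \code{"imaging"} or \code{"photometry"}.
#' @param manipulation one of \code{"drinking"}, \code{"ig_infusion"},
#'   \code{"ip_injection"}, \code{"closed_loop_training"}.
#' @param preset \code{"start_anchored"} (default) or
#'   \code{"legacy_end_anchored"}.
#' @param oral_s oral window length, seconds (default 30).
#' @param baseline_min baseline length before the anchor, minutes (default 10).
#' @return data.frame of class \code{epoch_set} with \code{label},
#'   \code{start_s}, \code{end_s}; attributes \code{"anchor_s"},
#'   \code{"modality"}, \code{"preset"}.
#' @export
define_epochs <- function(events, modality, manipulation,
                          preset = c("start_anchored", "legacy_end_anchored"),
                          oral_s = 30, baseline_min = 10) {
  modality <- match.arg(modality, MODALITIES)
  manipulation <- match.arg(manipulation, MANIPULATIONS)
  preset <- match.arg(preset)
  rows <- list()
  add <- function(label, start_s, end_s) {
    rows[[length(rows) + 1L]] <<- data.frame(label = label, start_s = start_s,
                                             end_s = end_s,
                                             stringsAsFactors = FALSE)
  }
  sys_end_min <- if (modality == "imaging") 32 else 50

  if (manipulation == "ip_injection") {
    inj <- events_of(events, "injection")
    if (!length(inj)) stop("missing anchor: no injection event")
    anchor <- inj[1]
    add("ip_systemic", anchor, anchor + 30 * 60)
  } else if (manipulation == "ig_infusion") {
    st <- events_of(events, "infusion_start")
    if (!length(st)) stop("missing anchor: no infusion_start event")
    anchor <- st[1]
    if (preset == "start_anchored") {
      add("gastrointestinal", anchor, anchor + 12 * 60)
      add("systemic", anchor + 12 * 60, anchor + sys_end_min * 60)
    } else {
      sp <- events_of(events, "infusion_stop")
      if (!length(sp)) stop("missing anchor: no infusion_stop event")
      add("post_ingestion", sp[1], sp[1] + 20 * 60)
    }
  } else { # drinking / closed_loop_training: anchored at the first lick bout
    b <- detect_bouts(events)
    if (!nrow(b)) stop("missing anchor: no lick bout in events")
    anchor <- b$start_s[1]
    add("oral", anchor, anchor + oral_s)
    if (preset == "start_anchored") {
      add("systemic", anchor + 12 * 60, anchor + sys_end_min * 60)
    } else {
      acc_stop <- events_of(events, "access_stop")
      if (!length(acc_stop)) stop("missing anchor: no access_stop event")
      add("post_ingestion", acc_stop[1], acc_stop[1] + 20 * 60)
    }
  }
  if (anchor > 0) add("baseline", max(0, anchor - baseline_min * 60), anchor)
  out <- do.call(rbind, rows)
  if (any(out$end_s <= out$start_s)) stop("epochs must have positive length")
  class(out) <- c("epoch_set", "data.frame")
  attr(out, "anchor_s") <- anchor
  attr(out, "modality") <- modality
  attr(out, "preset") <- preset
  out
}

#' Mean normalized response per neuron per epoch
#'
#' The response to an epoch is the arithmetic mean of the normalized signal
#' (z-score or dF/F0) over the samples in the half-open window
#' \code{[start_s, end_s)}. Because baseline z-scores average to zero by
#' construction, this mean is directly the "mean change of activity".
#'
#' @param z a \code{z_trace_matrix}, \code{dff_trace}, or numeric vector with
#'   \code{sample_rate}.
#' @param epochs an \code{\link{epoch_set}} or data.frame with \code{label},
#'   \code{start_s}, \code{end_s}.
#' @param sample_rate required when \code{z} is a bare numeric vector.
#' @param rebaseline_window optional length-2 window (seconds); if given, each
#'   neuron's mean over this window is subtracted from its epoch means —
#'   useful when the recording's baseline drifts and "change" should be
#'   measured against a window just before the anchor instead of the global
#'   baseline.
#' @return a numeric matrix, neurons x epochs (epoch labels as columns). For a
#'   single photometry trace the matrix has one row.
#' @export
epoch_response <- function(z, epochs, sample_rate = NULL,
                           rebaseline_window = NULL) {
  if (inherits(z, "z_trace_matrix")) {
    vals <- z$values; fs <- z$sample_rate; ids <- z$neuron_ids
  } else if (inherits(z, "dff_trace")) {
    vals <- matrix(z$values, nrow = 1, dimnames = list("signal", NULL))
    fs <- z$sample_rate; ids <- "signal"
  } else {
    if (is.null(sample_rate)) stop("supply `sample_rate` for a bare vector")
    vals <- if (is.matrix(z)) z else matrix(z, nrow = 1)
    fs <- sample_rate
    ids <- rownames(vals) %||% paste0("n", seq_len(nrow(vals)))
  }
  n_samp <- ncol(vals)
  out <- sapply(seq_len(nrow(epochs)), function(j) {
    idx <- window_index(epochs$start_s[j], epochs$end_s[j], fs, n_samp)
    if (!length(idx))
      stop("epoch '", epochs$label[j], "' contains no samples")
    rowMeans(vals[, idx, drop = FALSE], na.rm = TRUE)
  })
  out <- matrix(out, nrow = nrow(vals),
                dimnames = list(ids, epochs$label))
  if (!is.null(rebaseline_window)) {
    idx <- window_index(rebaseline_window[1], rebaseline_window[2], fs,
                        n_samp)
    if (!length(idx)) stop("rebaseline window contains no samples")
    out <- out - rowMeans(vals[, idx, drop = FALSE], na.rm = TRUE)
  }
  out
}

#' Classify neurons as activated / inhibited / unresponsive per epoch
#'
#' A neuron is activated in an epoch if its mean change of activity exceeds
#' \code{+threshold} z-units (strictly), inhibited if more negative than
#' \code{-threshold}, otherwise unresponsive. In \code{"exclusive"} mode the
#' activated label additionally requires the epoch's mean to strictly exceed
#' the neuron's mean in every other (non-baseline) epoch, so a neuron is
#' attributed to the single stage that drives it hardest.
#'
#' @param responses neurons x epochs matrix from \code{\link{epoch_response}}
#'   (a \code{baseline} column, if present, is carried through but never
#'   labelled).
#' @param mode \code{"simple"} (default) or \code{"exclusive"}.
#' @param threshold z threshold, default 1.
#' @return character matrix of labels (\code{"activated"},
#'   \code{"inhibited"}, \code{"none"}), same shape as the response epochs.
#' @export
classify_responses <- function(responses, mode = c("simple", "exclusive"),
                               threshold = 1) {
  mode <- match.arg(mode)
  responses <- as.matrix(responses)
  resp_cols <- setdiff(colnames(responses), "baseline")
  m <- responses[, resp_cols, drop = FALSE]
  labels <- matrix("none", nrow(m), ncol(m), dimnames = dimnames(m))
  labels[m > threshold] <- "activated"
  labels[m < -threshold] <- "inhibited"
  if (mode == "exclusive" && ncol(m) > 1) {
    for (j in seq_len(ncol(m))) {
      others <- m[, -j, drop = FALSE]
      not_max <- apply(others, 1, max) >= m[, j]
      labels[labels[, j] == "activated" & not_max, j] <- "none"
    }
  }
  labels
}

#' Population-weighted z-score summary per epoch
#'
#' For each epoch: the fraction of neurons activated and inhibited, and the
#' population-weighted z-score of each group — the fraction multiplied by the
#' group's mean z-scored activity change (zero when the group is empty).
#'
#' @param responses neurons x epochs matrix of mean z changes.
#' @param labels matching label matrix from \code{\link{classify_responses}}.
#' @return data.frame of class \code{population_summary}: \code{epoch},
#'   \code{n}, \code{fraction_activated}, \code{fraction_inhibited},
#'   \code{weighted_z_activated}, \code{weighted_z_inhibited}.
#' @export
population_summary <- function(responses, labels) {
  responses <- as.matrix(responses)
  labels <- as.matrix(labels)
  epochs <- colnames(labels)
  if (nrow(labels) < 1) stop("population summary needs at least one neuron")
  rows <- lapply(epochs, function(ep) {
    r <- responses[, ep]; l <- labels[, ep]
    n <- length(l)
    f_act <- sum(l == "activated") / n
    f_inh <- sum(l == "inhibited") / n
    wz_act <- if (f_act > 0) f_act * mean(r[l == "activated"]) else 0
    wz_inh <- if (f_inh > 0) f_inh * mean(r[l == "inhibited"]) else 0
    data.frame(epoch = ep, n = n,
               fraction_activated = f_act, fraction_inhibited = f_inh,
               weighted_z_activated = wz_act, weighted_z_inhibited = wz_inh,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  class(out) <- c("population_summary", "data.frame")
  out
}
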