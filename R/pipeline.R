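# End-to-end orchestration: simulate -> normalize -> behaviour -> classify ->
# stats -> report.

#' Run one synthetic session end to end
#'
#' Simulates a session from a \code{\link{session_design}} (events, ground
#' truth population, traces), normalizes (baseline z-score), screens bleaching
#' artifacts, builds the stage epochs, classifies every neuron, summarizes the
#' population, optionally fits rise latencies for systemic responders, and
#' returns a machine-readable report including the generator ground truth for
#' recovery checks. The run is fully deterministic given the config.
#'
#' @param config list with elements: \code{design} (a
#'   \code{\link{session_design}}), \code{fractions} (archetype fractions for
#'   \code{\link{gen_population}}), \code{n_neurons}, \code{effect},
#'   \code{noise}, \code{solution} (infused solution label, default
#'   \code{"water"}), \code{bout_params}, \code{mode}
#'   (\code{"simple"}/\code{"exclusive"}), \code{threshold} (default 1),
#'   \code{epoch_preset}, \code{fit_rise} (logical, default FALSE),
#'   \code{rise_sample_rate} (Hz the trace is downsampled to before sigmoid
#'   fitting, default 0.5), \code{seed}.
#' @param out_dir optional directory; if given, the report (JSON), events
#'   (CSV) and response table (CSV) are written there.
#' @return a list of class \code{session_report}.
#' @export
run_session <- function(config, out_dir = NULL) {
  cfg <- utils::modifyList(
    list(n_neurons = 100, fractions = c(systemic_activated = 0.39),
         effect = list(), noise = list(), solution = "water",
         bout_params = list(), mode = "simple", threshold = 1,
         epoch_preset = "start_anchored", fit_rise = FALSE,
         rise_sample_rate = 0.5, seed = 1L),
    config)
  if (is.null(cfg$design)) stop("config must contain a `design`")
  design <- cfg$design
  stopifnot(inherits(design, "session_design"))

  # --- simulate
  events <- tryCatch(
    session_events(design, seed = cfg$seed, solution = cfg$solution,
                   bout_params = cfg$bout_params),
    error = function(e) stop("behaviour stage failed: ", conditionMessage(e),
                             call. = FALSE))
  # the anchor comes from behaviour (first bout / infusion / injection)
  tryCatch(anchor_time(events, design$manipulation),
           error = function(e) stop("behaviour stage failed: ",
                                    conditionMessage(e), call. = FALSE))
  truth <- gen_population(cfg$n_neurons, cfg$fractions, cfg$effect,
                          seed = cfg$seed)
  traces <- gen_traces(truth, events, design, cfg$noise, seed = cfg$seed)

  # --- normalize
  base_win <- c(0, design$baseline_min * 60)
  screen <- screen_bleaching(traces, base_win)
  keep <- traces$neuron_ids %in% screen$kept
  traces_kept <- trace_matrix(traces$values[keep, , drop = FALSE],
                              traces$sample_rate, traces$neuron_ids[keep])
  z <- zscore_traces(traces_kept, base_win)

  # --- behaviour
  bouts <- detect_bouts(events)

  # --- classify
  epochs <- define_epochs(events, design$modality, design$manipulation,
                          preset = cfg$epoch_preset,
                          baseline_min = design$baseline_min)
  responses <- epoch_response(z, epochs)
  labels <- classify_responses(responses, mode = cfg$mode,
                               threshold = cfg$threshold)
  pop <- population_summary(responses[, colnames(labels), drop = FALSE],
                            labels)

  # --- truth recovery (classified vs injected fractions)
  truth_kept <- truth[match(z$neuron_ids, truth$neuron_id), ]
  recovery <- fraction_recovery(labels, truth_kept)

  # --- rise latency for systemic responders
  rise <- NULL
  if (isTRUE(cfg$fit_rise) && "systemic" %in% colnames(labels)) {
    anchor_s <- attr(epochs, "anchor_s")
    rise <- fit_systemic_latencies(z, labels, anchor_s,
                                   cfg$rise_sample_rate)
  }

  report <- structure(list(
    config = list(modality = design$modality,
                  manipulation = design$manipulation,
                  duration_min = design$duration_min,
                  sample_rate = design$sample_rate,
                  baseline_min = design$baseline_min,
                  infusion_rate_ul_min = design$infusion_rate_ul_min,
                  infusion_volume_ul = design$infusion_volume_ul,
                  n_neurons = cfg$n_neurons,
                  fractions = as.list(cfg$fractions),
                  mode = cfg$mode, threshold = cfg$threshold,
                  epoch_preset = cfg$epoch_preset, seed = cfg$seed),
    epochs = as.data.frame(epochs),
    anchor_s = attr(epochs, "anchor_s"),
    n_bouts = nrow(bouts),
    first_bout_start = attr(bouts, "first_bout_start") %||% NA_real_,
    excluded_bleaching = screen$excluded,
    excluded_degenerate = z$excluded$neuron_id,
    responses = as.data.frame(responses),
    labels = as.data.frame(labels),
    population = as.data.frame(pop),
    recovery = recovery,
    rise = rise,
    truth = as.data.frame(truth)),
    class = "session_report")

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_event_log(events, file.path(out_dir, "events.csv"))
    resp_out <- cbind(neuron_id = rownames(responses),
                      as.data.frame(responses),
                      setNames(as.data.frame(labels),
                               paste0("label_", colnames(labels))))
    utils::write.csv(resp_out, file.path(out_dir, "responses.csv"),
                     row.names = FALSE)
    write_json_sidecar(report, file.path(out_dir, "report.json"))
  }
  report
}

# Classified vs injected fraction per systemic/gi/oral archetype.
fraction_recovery <- function(labels, truth) {
  n <- nrow(labels)
  out <- list()
  if ("systemic" %in% colnames(labels)) {
    out$systemic_activated <- list(
      truth = mean(truth$archetype == "systemic_activated"),
      classified = mean(labels[, "systemic"] == "activated"))
    out$systemic_inhibited <- list(
      truth = mean(truth$archetype == "systemic_inhibited"),
      classified = mean(labels[, "systemic"] == "inhibited"))
  }
  if ("gastrointestinal" %in% colnames(labels))
    out$gi <- list(truth = mean(truth$archetype == "gi"),
                   classified = mean(labels[, "gastrointestinal"] ==
                                       "activated"))
  if ("oral" %in% colnames(labels))
    out$oral <- list(truth = mean(truth$archetype == "oral"),
                     classified = mean(labels[, "oral"] == "activated"))
  out
}

# Sigmoid latency fits for all classified systemic responders.
fit_systemic_latencies <- function(z, labels, anchor_s, fit_rate = 0.5) {
  sys_lab <- labels[, "systemic"]
  resp_idx <- which(sys_lab != "none")
  if (!length(resp_idx)) return(NULL)
  rows <- lapply(resp_idx, function(i) {
    tr <- z$values[i, ]
    ds <- downsample_series(tr, fit_rate, z$sample_rate)
    fit <- fit_rise(ds, fit_rate, anchor_s = anchor_s,
                    direction = if (sys_lab[i] == "activated") "activated"
                                else "inhibited")
    data.frame(neuron_id = z$neuron_ids[i], direction = sys_lab[i],
               t50_min = fit$t50_min, persistence_min = fit$persistence_min,
               r_squared = fit$r_squared, converged = fit$converged,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' @export
print.session_report <- function(x, ...) {
  cat(sprintf("<session_report> %s/%s, %d neurons (%d bleach-excluded)\n",
              x$config$modality, x$config$manipulation, x$config$n_neurons,
              length(x$excluded_bleaching)))
  print(x$population)
  invisible(x)
}

#' Run a closed-loop flavour-preference training experiment
#'
#' Simulates (or accepts) a training cohort, computes each mouse's pre- and
#' post-training preference for its water-paired flavour from the pooled
#' two-day two-bottle tests, runs a paired permutation test on the change,
#' and summarizes per-day consumption.
#'
#' @param config list: \code{n_per_group} (default 3), \code{learning}
#'   (see \code{\link{gen_training_cohort}}), \code{sides} (permutation test
#'   sidedness, default 2), \code{n_iter} (default 10000), \code{seed};
#'   alternatively supply \code{cohort}, an existing
#'   \code{\link{gen_training_cohort}} dataset.
#' @return a list of class \code{training_report}: \code{preference}
#'   (per-mouse pre/post water-paired preference), \code{consumption},
#'   \code{test} (the paired \code{\link{permutation_test}} on post - pre),
#'   \code{mean_change}.
#' @export
run_training_experiment <- function(config = list()) {
  cfg <- utils::modifyList(
    list(n_per_group = 3, learning = list(), sides = 2, n_iter = 10000,
         seed = 1L),
    config)
  cohort <- cfg$cohort %||%
    gen_training_cohort(cfg$n_per_group, cfg$learning, seed = cfg$seed)
  truth <- attr(cohort, "truth")

  pref <- do.call(rbind, lapply(cohort$mice, function(m) {
    wf <- names(m$map)[m$map == "water"]
    data.frame(mouse_id = m$mouse_id, group = m$group, water_flavour = wf,
               pre = pool_two_bottle(m$pre, wf),
               post = pool_two_bottle(m$post, wf),
               stringsAsFactors = FALSE)
  }))
  rownames(pref) <- NULL
  pref$change <- pref$post - pref$pre

  test <- NULL
  if (nrow(pref) >= 2) {
    test <- permutation_test(pref$post, pref$pre, paired = TRUE,
                             sides = cfg$sides, n_iter = cfg$n_iter,
                             seed = cfg$seed)
  } else {
    warning("fewer than 2 mice; preference reported without a test")
  }
  structure(list(preference = pref,
                 consumption = consumption_summary(cohort),
                 test = test,
                 mean_change = mean(pref$change),
                 truth = truth),
            class = "training_report")
}

#' @export
print.training_report <- function(x, ...) {
  cat(sprintf("<training_report> %d mice: mean preference change %+.3f",
              nrow(x$preference), x$mean_change))
  if (!is.null(x$test)) cat(sprintf(" (paired p = %.4g)", x$test$p_value))
  cat("\n")
  invisible(x)
}
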