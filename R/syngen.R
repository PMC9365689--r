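# Seeded synthetic-session generators with ground truth.
#
# Every generator draws from a substream derived from (seed, key) so adding
# entities (neurons, mice) never perturbs the draws of existing ones.

#' Generate a bout-structured lick train with known bout boundaries
#'
#' Produces lick events inside an access window, organised into runs separated
#' by gaps longer than the bout-splitting gap, so that the ground-truth bout
#' segmentation is known by construction: within a run every inter-lick
#' interval is strictly below \code{max_gap}, and consecutive runs are
#' separated by at least \code{gap_s[1] > max_gap}. Runs spanning
#' \code{>= min_duration} seconds are recorded as true bouts.
#'
#' @param design a \code{\link{session_design}}.
#' @param bout_params list with elements \code{lick_rate_hz} (mean lick rate
#'   within a run; 0 gives an empty train), \code{run_duration_s} length-2
#'   range of run durations, \code{gap_s} length-2 range of inter-run gaps
#'   (must exceed \code{max_gap}), \code{access} length-2 access window in
#'   seconds (default: 5 min starting at the end of the baseline), and the
#'   bout definition \code{min_duration} (10) and \code{max_gap} (2).
#' @param seed integer seed.
#' @return an \code{\link{event_log}} of lick plus access events, with
#'   attribute \code{"bouts"}: a data.frame of every generated run
#'   (\code{start_s}, \code{end_s}, \code{n_licks}, \code{is_bout}).
#' @export
gen_lick_train <- function(design, bout_params = list(), seed = 1L) {
  stopifnot(inherits(design, "session_design"))
  p <- utils::modifyList(
    list(lick_rate_hz = 6,
         run_duration_s = c(5, 25),
         gap_s = c(4, 30),
         access = NULL,
         min_duration = 10,
         max_gap = 2),
    bout_params)
  dur_s <- design$duration_min * 60
  if (is.null(p$access))
    p$access <- c(design$baseline_min * 60,
                  min(dur_s, design$baseline_min * 60 + 300))
  if (p$access[1] < 0 || p$access[2] > dur_s || p$access[1] >= p$access[2])
    stop("access window must lie inside the session")
  if (p$gap_s[1] <= p$max_gap)
    stop("inter-run gaps must exceed `max_gap` to keep runs separable")
  if (p$lick_rate_hz < 0) stop("lick rate must be >= 0")

  runs <- list()
  licks <- numeric(0)
  if (p$lick_rate_hz > 0) {
    with_substream(derive_seed(design$seed, "licks"), paste0("train/", seed), {
      t <- p$access[1]
      repeat {
        run_len <- runif(1, p$run_duration_s[1], p$run_duration_s[2])
        # inter-lick intervals strictly below max_gap
        mean_ili <- 1 / p$lick_rate_hz
        run <- numeric(0)
        tt <- t
        while (tt - t <= run_len && tt <= p$access[2]) {
          run <- c(run, tt)
          ili <- runif(1, 0.5 * mean_ili,
                       min(1.5 * mean_ili, 0.95 * p$max_gap))
          tt <- tt + ili
        }
        if (length(run) >= 1) {
          runs[[length(runs) + 1L]] <-
            data.frame(start_s = run[1], end_s = run[length(run)],
                       n_licks = length(run))
          licks <- c(licks, run)
        }
        t <- tt + runif(1, p$gap_s[1], p$gap_s[2])
        if (t > p$access[2]) break
      }
    })
  }
  bouts <- if (length(runs)) do.call(rbind, runs) else
    data.frame(start_s = numeric(0), end_s = numeric(0),
               n_licks = integer(0))
  bouts$is_bout <- (bouts$end_s - bouts$start_s) >= p$min_duration
  ev <- bind_events(
    event_log(p$access, c("access_start", "access_stop")),
    if (length(licks)) event_log(licks, rep("lick", length(licks)))
  )
  attr(ev, "bouts") <- bouts
  ev
}

#' Generate a ground-truth neural population by archetype
#'
#' Assigns each of \code{n_neurons} simulated neurons one of five archetypes
#' (oral, gastrointestinal, systemic activated, systemic inhibited, none) with
#' counts fixed by the largest-remainder rounding of the requested fractions
#' (ties broken in that archetype order; the unassigned remainder is
#' \code{"none"}). Systemic onsets and persistences are drawn from truncated
#' normal distributions around the supplied means.
#'
#' @param n_neurons number of neurons.
#' @param fractions named numeric vector of archetype fractions over
#'   \code{c("oral","gi","systemic_activated","systemic_inhibited")};
#'   non-negative, sum <= 1.
#' @param effect list of distribution settings: \code{onset_mean_min} /
#'   \code{onset_sd_min} (systemic onset after the anchor; defaults 14 and 1,
#'   the infusion values — use 10.1 for self-paced drinking),
#'   \code{persistence_mean_min} / \code{persistence_sd_min} (defaults 30 and
#'   0.7), \code{amplitude_z} named per-archetype mean peak amplitudes in
#'   z-units, \code{amplitude_jitter} multiplicative uniform half-range.
#' @param seed integer seed.
#' @return data.frame of class \code{ground_truth} with one row per neuron:
#'   \code{neuron_id}, \code{archetype}, \code{onset_min},
#'   \code{peak_amplitude}, \code{persistence_min}.
#' @export
gen_population <- function(n_neurons, fractions = c(systemic_activated = 0.39),
                           effect = list(), seed = 1L) {
  stopifnot(n_neurons >= 1)
  if (any(fractions < 0)) stop("fractions must be non-negative")
  if (sum(fractions) > 1 + 1e-12) stop("fractions must sum to <= 1")
  bad <- setdiff(names(fractions), ARCHETYPES)
  if (length(bad)) stop("unknown archetype(s): ", paste(bad, collapse = ", "))
  e <- utils::modifyList(
    list(onset_mean_min = 14, onset_sd_min = 1,
         persistence_mean_min = 30, persistence_sd_min = 0.7,
         amplitude_z = c(oral = 3, gi = 3, systemic_activated = 4,
                         systemic_inhibited = 4, none = 0),
         amplitude_jitter = 0.15),
    effect)

  counts <- largest_remainder(fractions, n_neurons)
  archetype <- rep("none", n_neurons)
  i <- 1L
  for (a in names(counts)) {
    k <- counts[[a]]
    if (k > 0) { archetype[i:(i + k - 1L)] <- a; i <- i + k }
  }

  truth <- with_substream(seed, "population", {
    onset <- ifelse(
      startsWith(archetype, "systemic"),
      pmin(pmax(rnorm(n_neurons, e$onset_mean_min, e$onset_sd_min),
                e$onset_mean_min - 3 * max(e$onset_sd_min, 1e-9)),
           e$onset_mean_min + 3 * max(e$onset_sd_min, 1e-9)),
      0)
    persistence <- ifelse(
      startsWith(archetype, "systemic"),
      pmin(pmax(rnorm(n_neurons, e$persistence_mean_min,
                      e$persistence_sd_min),
                e$persistence_mean_min - 3 * max(e$persistence_sd_min, 1e-9)),
           e$persistence_mean_min + 3 * max(e$persistence_sd_min, 1e-9)),
      0)
    amp <- e$amplitude_z[archetype] *
      runif(n_neurons, 1 - e$amplitude_jitter, 1 + e$amplitude_jitter)
    data.frame(neuron_id = paste0("n", seq_len(n_neurons)),
               archetype = archetype,
               onset_min = onset,
               peak_amplitude = unname(amp),
               persistence_min = persistence,
               stringsAsFactors = FALSE)
  })
  class(truth) <- c("ground_truth", "data.frame")
  attr(truth, "effect") <- e
  truth
}

# Largest-remainder apportionment of n among named fractions; ties broken by
# ARCHETYPES order. The remainder (1 - sum(fractions)) is left unassigned.
largest_remainder <- function(fractions, n) {
  fr <- fractions[intersect(ARCHETYPES, names(fractions))]
  quota <- fr * n
  base <- floor(quota + 1e-9)
  left <- round(sum(quota)) - sum(base)
  rem <- quota - base
  counts <- base
  if (left > 0) {
    ord <- order(-rem, match(names(fr), ARCHETYPES))
    counts[ord[seq_len(left)]] <- counts[ord[seq_len(left)]] + 1
  }
  as.list(counts)
}

# Unit-peak calcium transient kernel: exponential rise and decay.
transient_kernel <- function(sample_rate, tau_rise = 0.1, tau_decay = 1.0) {
  if (sample_rate < 2 / tau_decay)
    stop("sample_rate too low to resolve the requested transient kinetics")
  t <- seq(0, 6 * tau_decay, by = 1 / sample_rate)
  k <- (1 - exp(-t / tau_rise)) * exp(-t / tau_decay)
  k / max(k)
}

# Logistic plateau waveform on a time axis in minutes from the anchor:
# rises to 1 at `onset` (midpoint), decays through 0.5 at onset+persistence.
systemic_waveform <- function(t_min, onset, persistence,
                              rise_tau = 1.0, decay_tau = 2.0) {
  stats::plogis((t_min - onset) / rise_tau) *
    stats::plogis((onset + persistence - t_min) / decay_tau)
}

# Smooth box between on and off (minutes), soft edges tau (minutes).
window_waveform <- function(t_min, on, off, tau = 0.25) {
  stats::plogis((t_min - on) / tau) * stats::plogis((off - t_min) / tau)
}

# Anchor time (seconds) for a manipulation, from an event log.
anchor_time <- function(events, manipulation,
                        min_duration = 10, max_gap = 2) {
  switch(manipulation,
    ig_infusion = ,
    closed_loop_training = {
      t <- events_of(events, "infusion_start")
      if (!length(t)) stop("no infusion_start event to anchor on")
      t[1]
    },
    ip_injection = {
      t <- events_of(events, "injection")
      if (!length(t)) stop("no injection event to anchor on")
      t[1]
    },
    drinking = {
      b <- detect_bouts(events, min_duration = min_duration,
                        max_gap = max_gap)
      if (!nrow(b)) stop("no lick bout to anchor on")
      b$start_s[1]
    },
    stop("unknown manipulation: ", manipulation))
}

# Per-archetype unit waveforms (pre-amplitude) over the sample grid.
archetype_waveform <- function(archetype, t_s, anchor_s, events, design,
                               kinetics) {
  t_min <- (t_s - anchor_s) / 60
  switch(archetype,
    none = numeric(length(t_s)),
    oral = {
      licks <- events_of(events, "lick")
      x <- numeric(length(t_s))
      if (length(licks)) {
        idx <- pmin(length(t_s),
                    pmax(1L, floor(licks * design$sample_rate) + 1L))
        x[idx] <- x[idx] + 1
        k <- transient_kernel(design$sample_rate,
                              kinetics$tau_rise, kinetics$tau_decay)
        x <- as.numeric(stats::filter(c(x, numeric(length(k))), k,
                                      method = "convolution", sides = 1))
        x <- x[seq_along(t_s)]
        x[is.na(x)] <- 0
      }
      x
    },
    gi = {
      on <- events_of(events, "infusion_start")
      off <- events_of(events, "infusion_stop")
      if (!length(on)) return(numeric(length(t_s)))
      # elevated while fluid enters and sits in the gut
      window_waveform(t_min, (on[1] - anchor_s) / 60,
                      (off[1] - anchor_s) / 60 + kinetics$gi_tail_min)
    },
    systemic_activated = ,
    systemic_inhibited = {
      systemic_waveform(t_min, kinetics$onset_min, kinetics$persistence_min,
                        kinetics$rise_tau_min, kinetics$decay_tau_min)
    },
    stop("unknown archetype: ", archetype))
}

#' Simulate calcium traces for a ground-truth population
#'
#' Each neuron's raw trace is a constant photon baseline plus its archetype
#' waveform scaled to the requested z-amplitude, plus white noise, a slow
#' drift, and (for neurons selected as bleaching artifacts) an additive
#' decaying exponential. Oral responders emit per-lick calcium transients;
#' gastrointestinal responders are elevated while the infusion runs; systemic
#' responders follow a logistic ramp with midpoint at their ground-truth onset
#' and a logistic decay with midpoint at onset + persistence; inhibited
#' systemic neurons are the mirrored waveform, tracking the session's latent
#' osmolality record.
#'
#' @param truth a \code{\link{gen_population}} ground truth.
#' @param events an \code{\link{event_log}} covering the session.
#' @param design a \code{\link{session_design}} (imaging modality).
#' @param noise list: \code{sd} white-noise sd in raw units (z-amplitudes are
#'   expressed relative to this; 0 gives noiseless traces), \code{drift_sd}
#'   slow random-walk drift sd per sqrt(minute), \code{n_bleach} number of
#'   neurons given a bleaching exponential, \code{bleach_amp} its amplitude in
#'   baseline-sd units, \code{bleach_tau_min} its time constant,
#'   \code{tau_rise}/\code{tau_decay} transient kinetics (s),
#'   \code{rise_tau_min}/\code{decay_tau_min} systemic logistic scales,
#'   \code{gi_tail_min} decay allowance after infusion stop.
#' @param seed integer seed.
#' @return a \code{\link{trace_matrix}} with attributes \code{"bleach_ids"}
#'   (neurons carrying the bleaching artifact) and \code{"osmolality"} (the
#'   session's latent osmolality-like curve, arbitrary units).
#' @export
gen_traces <- function(truth, events, design, noise = list(), seed = 1L) {
  stopifnot(inherits(truth, "ground_truth"),
            inherits(design, "session_design"))
  p <- utils::modifyList(
    list(sd = 1, drift_sd = 0.05, n_bleach = 0, bleach_amp = 8,
         bleach_tau_min = 3, tau_rise = 0.1, tau_decay = 1.0,
         rise_tau_min = 1.0, decay_tau_min = 2.0, gi_tail_min = 1.0,
         baseline_level = 10),
    noise)
  fs <- design$sample_rate
  n_samp <- floor(design$duration_min * 60 * fs)
  t_s <- (seq_len(n_samp) - 1) / fs
  anchor_s <- anchor_time(events, design$manipulation)
  scale <- if (p$sd > 0) p$sd else 1

  bleach_ids <- character(0)
  if (p$n_bleach > 0) {
    bleach_ids <- with_substream(seed, "bleach-pick",
      sample(truth$neuron_id, min(p$n_bleach, nrow(truth))))
  }

  values <- matrix(0, nrow(truth), n_samp,
                   dimnames = list(truth$neuron_id, NULL))
  for (i in seq_len(nrow(truth))) {
    kin <- list(tau_rise = p$tau_rise, tau_decay = p$tau_decay,
                onset_min = truth$onset_min[i],
                persistence_min = truth$persistence_min[i],
                rise_tau_min = p$rise_tau_min,
                decay_tau_min = p$decay_tau_min,
                gi_tail_min = p$gi_tail_min)
    wave <- archetype_waveform(truth$archetype[i], t_s, anchor_s, events,
                               design, kin)
    sign <- if (truth$archetype[i] == "systemic_inhibited") -1 else 1
    sig <- p$baseline_level + sign * truth$peak_amplitude[i] * scale * wave
    sig <- sig + with_substream(seed, paste0("noise/", truth$neuron_id[i]), {
      eps <- if (p$sd > 0) rnorm(n_samp, 0, p$sd) else numeric(n_samp)
      drift <- if (p$drift_sd > 0) {
        w <- cumsum(rnorm(n_samp, 0, p$drift_sd / sqrt(60 * fs)))
        w - mean(w[seq_len(max(1L, floor(design$baseline_min * 60 * fs)))])
      } else numeric(n_samp)
      eps + drift
    })
    if (truth$neuron_id[i] %in% bleach_ids) {
      amp <- p$bleach_amp * scale
      sig <- sig + amp * exp(-t_s / (p$bleach_tau_min * 60))
    }
    values[i, ] <- sig
  }

  tm <- trace_matrix(values, fs, truth$neuron_id)
  attr(tm, "bleach_ids") <- bleach_ids
  attr(tm, "osmolality") <- osmolality_latent(t_s, anchor_s, design, events)
  attr(tm, "anchor_s") <- anchor_s
  tm
}

# Latent osmolality-like record: piecewise-linear fall (water) or rise
# (hypertonic saline) starting as absorption begins, plateauing afterwards;
# magnitude scales with delivered volume (1 at 1.2 ml).
osmolality_latent <- function(t_s, anchor_s, design, events,
                              absorb_start_min = 10, absorb_end_min = 25) {
  t_min <- (t_s - anchor_s) / 60
  vol <- design$infusion_volume_ul %||% 1200
  sol <- events$solution[events$kind %in% c("infusion_start", "injection")]
  hypertonic <- length(sol) && any(grepl("NaCl|saline", sol, ignore.case = TRUE) &
                                     !grepl("154|isotonic", sol))
  ramp <- pmin(1, pmax(0, (t_min - absorb_start_min) /
                         (absorb_end_min - absorb_start_min)))
  (if (hypertonic) 1 else -1) * (vol / 1200) * ramp
}

# Standard event scaffold for a designed session (infusion/injection timing).
session_events <- function(design, seed = 1L, solution = "water",
                           bout_params = list()) {
  base_s <- design$baseline_min * 60
  switch(design$manipulation,
    drinking = gen_lick_train(design, bout_params, seed = seed),
    ig_infusion = {
      dur_s <- design$infusion_volume_ul / design$infusion_rate_ul_min * 60
      event_log(c(base_s, base_s + dur_s),
                c("infusion_start", "infusion_stop"),
                solution = solution,
                volume_ul = c(design$infusion_volume_ul, NA))
    },
    ip_injection = event_log(base_s, "injection", solution = solution),
    closed_loop_training = {
      ev <- gen_lick_train(design, bout_params, seed = seed)
      licks <- events_of(ev, "lick")
      bind_events(ev, closed_loop_infusions(licks, solution))
    })
}

# Closed-loop rule: every lick triggers a 1 ul infusion of the mapped
# solution (start/stop pairs 0.5 s apart, matching the brief pump pulse).
closed_loop_infusions <- function(lick_times, solution, pulse_s = 0.5) {
  if (!length(lick_times)) return(event_log())
  event_log(c(lick_times, lick_times + pulse_s),
            c(rep("infusion_start", length(lick_times)),
              rep("infusion_stop", length(lick_times))),
            solution = solution,
            volume_ul = c(rep(1, length(lick_times)),
                          rep(NA, length(lick_times))))
}

#' Simulate a dual-channel photometry session
#'
#' The signal channel carries a stage-weighted response riding on its
#' baseline; both channels share a slow motion-artifact random walk (with
#' channel-specific gain) plus independent white noise, so isosbestic
#' regression can remove the artifact but not the response.
#'
#' @param region_profile named weights \code{c(oral=, gi=, systemic=)} giving
#'   the fractional fluorescence response of this recording site per stage.
#' @param events an \code{\link{event_log}}.
#' @param design a photometry \code{\link{session_design}}.
#' @param artifact list: \code{walk_sd} random-walk artifact sd per
#'   sqrt(minute) in baseline units, \code{gain_signal} / \code{gain_reference}
#'   channel gains for the shared artifact, \code{noise_sd} white-noise sd,
#'   \code{base_signal} / \code{base_reference} channel baselines,
#'   \code{onset_min} / \code{persistence_min} systemic timing.
#' @param seed integer seed.
#' @return a \code{\link{photometry_signal}} with attribute
#'   \code{"artifact"} (the injected common-mode artifact) and
#'   \code{"response"} (the injected fractional response).
#' @export
gen_photometry <- function(region_profile, events, design, artifact = list(),
                           seed = 1L) {
  stopifnot(inherits(design, "session_design"))
  if (!all(is.finite(region_profile))) stop("region weights must be finite")
  p <- utils::modifyList(
    list(walk_sd = 0.5, gain_signal = 1, gain_reference = 0.8,
         noise_sd = 0.01, base_signal = 100, base_reference = 60,
         onset_min = 14, persistence_min = 30,
         rise_tau_min = 1.0, decay_tau_min = 2.0, gi_tail_min = 1.0,
         tau_rise = 0.1, tau_decay = 1.0),
    artifact)
  fs <- design$sample_rate
  n <- floor(design$duration_min * 60 * fs)
  t_s <- (seq_len(n) - 1) / fs
  anchor_s <- anchor_time(events, design$manipulation)

  w <- function(nm) unname(region_profile[nm] %||% 0)
  wts <- c(oral = if ("oral" %in% names(region_profile)) region_profile[["oral"]] else 0,
           gi = if ("gi" %in% names(region_profile)) region_profile[["gi"]] else 0,
           systemic = if ("systemic" %in% names(region_profile)) region_profile[["systemic"]] else 0)
  kin <- list(tau_rise = p$tau_rise, tau_decay = p$tau_decay,
              onset_min = p$onset_min, persistence_min = p$persistence_min,
              rise_tau_min = p$rise_tau_min, decay_tau_min = p$decay_tau_min,
              gi_tail_min = p$gi_tail_min)
  resp <- numeric(n)
  if (wts[["oral"]] != 0)
    resp <- resp + wts[["oral"]] *
      archetype_waveform("oral", t_s, anchor_s, events, design, kin)
  if (wts[["gi"]] != 0 && length(events_of(events, "infusion_start")))
    resp <- resp + wts[["gi"]] *
      archetype_waveform("gi", t_s, anchor_s, events, design, kin)
  if (wts[["systemic"]] != 0)
    resp <- resp + wts[["systemic"]] *
      archetype_waveform("systemic_activated", t_s, anchor_s, events, design,
                         kin)

  out <- with_substream(seed, "photometry", {
    art <- if (p$walk_sd > 0)
      cumsum(rnorm(n, 0, p$walk_sd / sqrt(60 * fs))) else numeric(n)
    art <- art - mean(art)
    sig <- p$base_signal * (1 + resp) + p$gain_signal * art +
      rnorm(n, 0, p$noise_sd)
    ref <- p$base_reference + p$gain_reference * art + rnorm(n, 0, p$noise_sd)
    list(sig = sig, ref = ref, art = art)
  })
  ps <- photometry_signal(out$sig, out$ref, fs)
  attr(ps, "artifact") <- out$art
  attr(ps, "response") <- resp
  attr(ps, "anchor_s") <- anchor_s
  ps
}

#' Simulate a 3-axis head-mounted accelerometer stream
#'
#' Rest segments are white noise at the floor level; movement segments add a
#' large low-frequency wobble plus extra noise on each axis.
#'
#' @param movement_bouts data.frame with \code{start_s}, \code{end_s} of
#'   movement periods (may be empty for an all-rest session).
#' @param duration_s total duration, seconds.
#' @param noise list: \code{floor_sd} rest noise sd, \code{move_sd} movement
#'   noise sd, \code{wobble_hz} movement oscillation frequency.
#' @param sample_rate Hz, default 50.
#' @param seed integer seed.
#' @return an \code{\link{accel_signal}} with attribute \code{"schedule"},
#'   the logical per-sample movement ground truth.
#' @export
gen_accelerometer <- function(movement_bouts, duration_s, noise = list(),
                              sample_rate = 50, seed = 1L) {
  p <- utils::modifyList(
    list(floor_sd = 0.02, move_sd = 1.0, wobble_hz = 2), noise)
  n <- floor(duration_s * sample_rate)
  t_s <- (seq_len(n) - 1) / sample_rate
  moving <- rep(FALSE, n)
  if (nrow(movement_bouts)) {
    if (any(movement_bouts$start_s < 0 | movement_bouts$end_s > duration_s))
      stop("movement schedule must lie inside the session")
    for (i in seq_len(nrow(movement_bouts)))
      moving <- moving | (t_s >= movement_bouts$start_s[i] &
                            t_s < movement_bouts$end_s[i])
  }
  axes <- with_substream(seed, "accel", {
    m <- matrix(rnorm(3 * n, 0, p$floor_sd), nrow = 3)
    if (any(moving)) {
      for (ax in 1:3) {
        ph <- runif(1, 0, 2 * pi)
        m[ax, moving] <- m[ax, moving] +
          p$move_sd * sin(2 * pi * p$wobble_hz * t_s[moving] + ph) +
          rnorm(sum(moving), 0, p$move_sd / 2)
      }
    }
    m
  })
  sig <- accel_signal(axes, sample_rate)
  attr(sig, "schedule") <- moving
  sig
}
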