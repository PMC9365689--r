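# Synthetic-session generators: determinism, ground-truth structure,
# waveform fidelity.

test_that("lick trains respect the access window and record their own bouts", {
  d <- session_design("imaging", 30, "drinking", seed = 2)
  ev <- gen_lick_train(d, seed = 1)
  licks <- ev$time_s[ev$kind == "lick"]
  acc <- ev$time_s[ev$kind %in% c("access_start", "access_stop")]
  expect_true(all(licks >= acc[1] & licks <= acc[2]))
  bouts <- attr(ev, "bouts")
  expect_true(all(c("start_s", "end_s", "n_licks", "is_bout") %in%
                    names(bouts)))
  # recorded truth equals the detector's segmentation
  det <- detect_bouts(ev)
  truth <- bouts[bouts$is_bout, ]
  expect_equal(det$start_s, truth$start_s)
  expect_equal(det$end_s, truth$end_s)
  expect_equal(det$n_licks, truth$n_licks)
})

test_that("zero lick rate gives an empty train and bad windows are rejected", {
  d <- session_design("imaging", 30, "drinking", seed = 2)
  ev <- gen_lick_train(d, list(lick_rate_hz = 0), seed = 1)
  expect_length(ev$time_s[ev$kind == "lick"], 0)
  expect_error(gen_lick_train(d, list(access = c(100, 40 * 60)), seed = 1),
               "inside the session")
})

test_that("generators are bit-identical under the same seed", {
  d <- session_design("imaging", 30, "drinking", seed = 9)
  expect_identical(gen_lick_train(d, seed = 4), gen_lick_train(d, seed = 4))
  expect_false(identical(gen_lick_train(d, seed = 4),
                         gen_lick_train(d, seed = 5)))
  tr1 <- gen_population(20, c(systemic_activated = 0.3), seed = 11)
  tr2 <- gen_population(20, c(systemic_activated = 0.3), seed = 11)
  expect_identical(tr1, tr2)
  s <- make_infusion_session(n_neurons = 5, seed = 3)
  s2 <- make_infusion_session(n_neurons = 5, seed = 3)
  expect_identical(s$traces$values, s2$traces$values)
})

test_that("archetype counts follow the largest-remainder rule", {
  tr <- gen_population(10, c(systemic_activated = 0.4), seed = 1)
  expect_equal(sum(tr$archetype == "systemic_activated"), 4)
  expect_equal(sum(tr$archetype == "none"), 6)
  tr2 <- gen_population(7, c(oral = 0.5, gi = 0.5), seed = 1)
  # quotas 3.5/3.5: one seat left, tie broken by archetype order (oral first)
  expect_equal(sum(tr2$archetype == "oral"), 4)
  expect_equal(sum(tr2$archetype == "gi"), 3)
  tr3 <- gen_population(8, c(oral = 0, gi = 0), seed = 1)
  expect_true(all(tr3$archetype == "none"))
  expect_error(gen_population(10, c(oral = -0.1)), "non-negative")
})

test_that("adding neurons does not perturb existing neurons' noise", {
  s <- make_infusion_session(n_neurons = 10, seed = 3)
  # extend the same population with extra unresponsive neurons
  extra <- s$truth[rep(1, 5), ]
  extra$neuron_id <- paste0("n", 11:15)
  extra$archetype <- "none"
  truth_big <- rbind(s$truth, extra)
  class(truth_big) <- class(s$truth)
  big <- gen_traces(truth_big, s$events, s$design, seed = 3)
  expect_identical(s$traces$values[1:10, ], big$values[1:10, ])
})

test_that("a noiseless flat neuron normalizes to z == 0", {
  s <- make_infusion_session(n_neurons = 3, seed = 5,
                             fractions = c(oral = 0),
                             noise = list(sd = 0, drift_sd = 0))
  z <- zscore_traces(s$traces, c(0, 600))
  expect_equal(max(abs(z$values)), 0)
})

test_that("noiseless systemic responders carry their injected onset", {
  s <- make_infusion_session(
    n_neurons = 2, seed = 5, fractions = c(systemic_activated = 1),
    noise = list(sd = 0, drift_sd = 0))
  anchor <- attr(s$traces, "anchor_s")
  for (i in 1:2) {
    y <- s$traces$values[i, ] - 10  # remove the photon baseline
    ds <- downsample_series(y, 0.5, s$traces$sample_rate)
    fit <- fit_rise(ds, 0.5, anchor_s = anchor, direction = "activated")
    expect_true(fit$converged)
    expect_lt(abs(fit$t50_min - s$truth$onset_min[i]), 1 / 15)
    expect_lt(abs(fit$persistence_min - s$truth$persistence_min[i]), 1)
  }
})

test_that("epoch means match the closed-form expectation of the waveform", {
  # fixed amplitude/onset, no jitter: the systemic epoch mean must equal the
  # analytic mean of the logistic-plateau waveform over the window
  eff <- list(onset_mean_min = 14, onset_sd_min = 0,
              persistence_mean_min = 30, persistence_sd_min = 0,
              amplitude_jitter = 0)
  means <- vapply(1:5, function(seed) {
    d <- session_design("imaging", 65, "ig_infusion",
                        infusion_rate_ul_min = 100,
                        infusion_volume_ul = 1200, seed = seed)
    ev <- ingestphase:::session_events(d)
    truth <- gen_population(20, c(systemic_activated = 1), eff, seed = seed)
    tr <- gen_traces(truth, ev, d, seed = seed)
    z <- zscore_traces(tr, c(0, 600))
    ep <- define_epochs(ev, "imaging", "ig_infusion")
    mean(epoch_response(z, ep)[, "systemic"])
  }, numeric(1))
  # analytic expectation written out independently of the generator code
  t_min <- seq(12, 32, by = 1 / 60 / 8)[-1]
  wave <- plogis((t_min - 14) / 1) * plogis((14 + 30 - t_min) / 2)
  expected <- 4 * mean(wave)
  expect_lt(abs(mean(means) - expected), 0.1)
})

test_that("photometry with no response and no artifact corrects to ~0 dF/F", {
  d <- session_design("photometry", 15, "ig_infusion", sample_rate = 20,
                      infusion_rate_ul_min = 100, infusion_volume_ul = 200,
                      seed = 1)
  ev <- ingestphase:::session_events(d)
  ph <- gen_photometry(c(oral = 0, gi = 0, systemic = 0), ev, d,
                       artifact = list(walk_sd = 0, noise_sd = 0.01),
                       seed = 1)
  dff <- dff_isosbestic(ph, c(0, 600))
  expect_lt(sd(dff$values, na.rm = TRUE), 5e-4)
})

test_that("oral-weight-only photometry peaks with licking, not late", {
  d <- session_design("photometry", 40, "drinking", sample_rate = 20, seed = 2)
  ev <- gen_lick_train(d, seed = 2)
  ph <- gen_photometry(c(oral = 0.1), ev, d,
                       artifact = list(walk_sd = 0, noise_sd = 0.005),
                       seed = 2)
  dff <- dff_isosbestic(ph, c(0, 600))
  ep <- define_epochs(ev, "photometry", "drinking")
  r <- epoch_response(dff, ep)
  expect_gt(r[, "oral"], 0.02)
  expect_lt(abs(r[, "systemic"]), 0.005)
  # the global peak is lick-locked: within 2 s after some lick
  pk_t <- (which.max(dff$values) - 1) / dff$sample_rate
  licks <- ev$time_s[ev$kind == "lick"]
  expect_lt(min(pk_t - licks[licks <= pk_t]), 2)
})

test_that("accelerometer schedules are recovered by movement segmentation", {
  sched <- data.frame(start_s = c(10, 30, 50), end_s = c(20, 40, 60))
  acc <- gen_accelerometer(sched, 70, seed = 1)
  seg <- movement_segments(acc)
  truth <- attr(acc, "schedule")
  # agreement away from edges (filter group delay): > 97% of samples
  expect_gt(mean(seg$moving == truth), 0.97)
})

test_that("all-rest accelerometer falls back to rest labels", {
  acc <- gen_accelerometer(data.frame(start_s = numeric(0),
                                      end_s = numeric(0)),
                           10, noise = list(floor_sd = 0), seed = 1)
  expect_warning(seg <- movement_segments(acc), "degenerate")
  expect_false(any(seg$moving))
})

test_that("closed-loop conservation: one 1-ul infusion per training lick", {
  cohort <- gen_training_cohort(2, seed = 3)
  cons <- consumption_summary(cohort)
  expect_equal(cons$infused_ul, cons$licks)
  d <- session_design("imaging", 30, "closed_loop_training", seed = 4)
  ev <- ingestphase:::session_events(d, solution = "water")
  n_licks <- sum(ev$kind == "lick")
  expect_equal(sum(ev$kind == "infusion_start"), n_licks)
  expect_equal(sum(ev$volume_ul[ev$kind == "infusion_start"]), n_licks * 1)
})

test_that("training drift model hits its closed-form expectation", {
  # deterministic extremes
  full <- gen_training_cohort(1, list(drift = 1, deterministic = TRUE),
                              seed = 1)
  for (m in full$mice) {
    wf <- names(m$map)[m$map == "water"]
    expect_equal(ingestphase:::pool_two_bottle(m$post, wf), 1.0)
  }
  none <- gen_training_cohort(1, list(drift = 0, deterministic = TRUE),
                              seed = 1)
  for (m in none$mice) {
    wf <- names(m$map)[m$map == "water"]
    expect_equal(ingestphase:::pool_two_bottle(m$post, wf),
                 ingestphase:::pool_two_bottle(m$pre, wf))
  }
  # stochastic: E[post - pre] = drift * (1 - p0_mean)
  drift <- 0.6
  changes <- vapply(1:10, function(seed) {
    rep <- run_training_experiment(list(n_per_group = 3,
                                        learning = list(drift = drift),
                                        n_iter = 99, seed = seed))
    rep$mean_change
  }, numeric(1))
  expect_lt(abs(mean(changes) - drift * (1 - 0.5)), 0.02)
})
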