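# Epochs, classification, population summary, rise fits, correlation,
# matching.

test_that("epoch windows match the stage definitions", {
  ev <- event_log(c(600, 1320), c("infusion_start", "infusion_stop"))
  ep <- define_epochs(ev, "imaging", "ig_infusion")
  expect_equal(ep$start_s[ep$label == "gastrointestinal"], 600)
  expect_equal(ep$end_s[ep$label == "gastrointestinal"], 1320)
  expect_equal(ep$start_s[ep$label == "systemic"], 1320)
  expect_equal(ep$end_s[ep$label == "systemic"], 600 + 32 * 60)
  expect_equal(ep$start_s[ep$label == "baseline"], 0)
  expect_equal(ep$end_s[ep$label == "baseline"], 600)

  ep_ph <- define_epochs(ev, "photometry", "ig_infusion")
  expect_equal(ep_ph$end_s[ep_ph$label == "systemic"], 600 + 50 * 60)

  inj <- event_log(600, "injection")
  ep_ip <- define_epochs(inj, "imaging", "ip_injection")
  expect_equal(ep_ip$start_s[ep_ip$label == "ip_systemic"], 600)
  expect_equal(ep_ip$end_s[ep_ip$label == "ip_systemic"], 600 + 30 * 60)

  # photometry drinking with the first bout at t = 0
  licks <- event_log(seq(0, 15, by = 1), rep("lick", 16))
  ep_dr <- define_epochs(licks, "photometry", "drinking")
  expect_equal(ep_dr$start_s[ep_dr$label == "systemic"], 720)
  expect_equal(ep_dr$end_s[ep_dr$label == "systemic"], 3000)
  expect_equal(ep_dr$start_s[ep_dr$label == "oral"], 0)

  expect_error(define_epochs(licks, "imaging", "ig_infusion"),
               "no infusion_start")
  expect_error(define_epochs(event_log(1, "lick"), "imaging", "drinking"),
               "no lick bout")
})

test_that("the legacy end-anchored preset uses 0-20 min post consumption", {
  ev <- event_log(c(600, 1320), c("infusion_start", "infusion_stop"))
  ep <- define_epochs(ev, "imaging", "ig_infusion",
                      preset = "legacy_end_anchored")
  expect_equal(ep$start_s[ep$label == "post_ingestion"], 1320)
  expect_equal(ep$end_s[ep$label == "post_ingestion"], 1320 + 20 * 60)
})

test_that("epoch responses are windowed means", {
  z <- structure(list(values = rbind(rep(2, 100)), sample_rate = 1,
                      neuron_ids = "a", baseline_window = c(0, 50),
                      mu = 0, sigma = 1,
                      excluded = data.frame(neuron_id = character(0),
                                            reason = character(0))),
                 class = "z_trace_matrix")
  ep <- data.frame(label = "w", start_s = 10, end_s = 60)
  expect_equal(unname(epoch_response(z, ep)[1, 1]), 2)
  # antisymmetric ramp about the window midpoint averages to zero
  ramp <- seq(-1, 1, length.out = 100)
  expect_equal(unname(epoch_response(ramp, data.frame(
    label = "w", start_s = 0, end_s = 100), sample_rate = 1)[1, 1]), 0,
    tolerance = 1e-12)
  # random traces vs a direct windowed-mean oracle
  withr::with_seed(8, {
    vals <- matrix(rnorm(5 * 200), 5)
    ep2 <- data.frame(label = c("a", "b"), start_s = c(13, 50),
                      end_s = c(87, 200))
    got <- epoch_response(vals, ep2, sample_rate = 1)
    expect_equal(got[, "a"], rowMeans(vals[, 14:87]),
                 ignore_attr = TRUE)
    expect_equal(got[, "b"], rowMeans(vals[, 51:200]),
                 ignore_attr = TRUE)
  })
  expect_error(epoch_response(ramp, data.frame(label = "x", start_s = 300,
                                               end_s = 400),
                              sample_rate = 1), "no samples")
  # re-baselining subtracts the pre-anchor window mean
  withr::with_seed(9, {
    v <- matrix(rnorm(2 * 100), 2)
    ep3 <- data.frame(label = "w", start_s = 50, end_s = 100)
    plain <- epoch_response(v, ep3, sample_rate = 1)
    reb <- epoch_response(v, ep3, sample_rate = 1,
                          rebaseline_window = c(0, 50))
    expect_equal(reb, plain - rowMeans(v[, 1:50]), ignore_attr = TRUE)
  })
})

test_that("classification applies strict +/-1z thresholds", {
  m <- rbind(n1 = c(oral = 1.5, gastrointestinal = 0.2, systemic = -1.5))
  lab <- classify_responses(m)
  expect_equal(unname(lab[1, ]), c("activated", "none", "inhibited"))
  # boundary exactly +1.0 is not activated ("exceeded")
  expect_equal(unname(classify_responses(rbind(c(oral = 1.0)))[1, 1]), "none")
  expect_equal(unname(classify_responses(rbind(c(oral = -1.0)))[1, 1]), "none")
})

test_that("exclusive mode keeps only the dominant epoch", {
  m <- rbind(n1 = c(oral = 1.5, gastrointestinal = 1.6))
  lab <- classify_responses(m, mode = "exclusive")
  expect_equal(unname(lab[1, ]), c("none", "activated"))
  # exclusive never labels more epochs activated than simple
  withr::with_seed(10, {
    for (k in 1:25) {
      mm <- matrix(rnorm(3 * 4, 0, 1.5), 3,
                   dimnames = list(NULL, c("oral", "gastrointestinal",
                                           "systemic", "baseline")))
      simple <- classify_responses(mm)
      excl <- classify_responses(mm, mode = "exclusive")
      expect_true(all(rowSums(excl == "activated") <=
                        rowSums(simple == "activated")))
    }
  })
})

test_that("raising an epoch mean never demotes an activated label", {
  withr::with_seed(12, {
    m <- matrix(rnorm(20, 0, 1.5), 10, 2,
                dimnames = list(NULL, c("a", "b")))
    base <- classify_responses(m)
    m2 <- m; m2[, 1] <- m2[, 1] + 0.7
    up <- classify_responses(m2)
    was_act <- base[, 1] == "activated"
    expect_true(all(up[was_act, 1] == "activated"))
  })
})

test_that("population summary computes fraction x group mean", {
  r <- matrix(c(rep(2, 4), rep(0, 6)), ncol = 1,
              dimnames = list(NULL, "systemic"))
  l <- matrix(c(rep("activated", 4), rep("none", 6)), ncol = 1,
              dimnames = list(NULL, "systemic"))
  ps <- population_summary(r, l)
  expect_equal(ps$fraction_activated, 0.4)
  expect_equal(ps$weighted_z_activated, 0.4 * 2)
  expect_equal(ps$weighted_z_inhibited, 0)  # empty group
  # random tables vs direct recomputation; permutation & duplication stable
  withr::with_seed(13, {
    rr <- matrix(rnorm(30, 0, 2), ncol = 1, dimnames = list(NULL, "e"))
    ll <- classify_responses(rr)
    ps1 <- population_summary(rr, ll)
    f <- mean(ll == "activated")
    expect_equal(ps1$fraction_activated, f)
    expect_equal(ps1$weighted_z_activated,
                 if (f > 0) f * mean(rr[ll == "activated"]) else 0)
    o <- sample(30)
    ps2 <- population_summary(rr[o, , drop = FALSE], ll[o, , drop = FALSE])
    expect_equal(ps1$fraction_activated, ps2$fraction_activated)
    expect_equal(ps1$weighted_z_activated, ps2$weighted_z_activated)
    dup <- rbind(rr, rr)
    pd <- population_summary(dup, classify_responses(dup))
    expect_equal(pd$fraction_activated, ps1$fraction_activated)
    expect_equal(pd$weighted_z_activated, ps1$weighted_z_activated)
  })
})

test_that("sigmoid fits recover a noiseless logistic and mirror under sign", {
  t_min <- seq(0, 50, by = 1 / 30)  # 0.5 Hz trace
  y <- 3 * plogis((t_min - 14) / 1.2)
  fit <- fit_rise(y, 0.5, anchor_s = 0, direction = "activated")
  expect_true(fit$converged)
  expect_lt(abs(fit$t50_min - 14), 1 / 30)
  fit_inh <- fit_rise(-y, 0.5, anchor_s = 0, direction = "inhibited")
  expect_lt(abs(fit_inh$t50_min - fit$t50_min), 1e-6)
  expect_error(fit_rise(y[1:50], 0.5, window_s = c(0, 100)), ">= 4 min")
})

test_that("matched-identity correlations behave at the extremes", {
  withr::with_seed(4, {
    a <- rnorm(6)
    same <- cross_condition_correlation(a, a)
    expect_equal(same$r, 1)
    expect_true(same$exact)
    neg <- cross_condition_correlation(a, -a)
    expect_equal(neg$r, -1)
    expect_error(cross_condition_correlation(a, rep(1, 6)), "zero variance")
    expect_error(cross_condition_correlation(a[1:2], a[1:2]), "at least 3")
  })
})

test_that("pairing permutation p equals full enumeration at n = 6", {
  withr::with_seed(19, {
    a <- rnorm(6); b <- 0.8 * a + rnorm(6, 0, 0.5)
    got <- cross_condition_correlation(a, b)
    perms <- all_perms(6)
    rs <- apply(perms, 1, function(p) cor(a, b[p]))
    want <- mean(abs(rs) >= abs(cor(a, b)) - 1e-12)
    expect_equal(got$p_value, want)
    expect_equal(got$n_iterations, 720)
  })
})

test_that("neuron matching is exact against brute force at n <= 6", {
  # identity
  withr::with_seed(15, {
    a <- matrix(runif(10, 0, 50), 5)
    m <- match_neurons(a, a, max_dist = 5)
    expect_equal(m$matches$index_a, 1:5)
    expect_equal(m$matches$index_b, 1:5)
    expect_equal(m$total_dist, 0)
    # a translation beyond max_dist empties the mapping
    far <- match_neurons(a, a + 100, max_dist = 5)
    expect_equal(nrow(far$matches), 0)
    expect_equal(far$unmatched_a, 1:5)
    # random cases vs exhaustive permutation search
    for (k in 1:20) {
      na <- sample(2:6, 1); nb <- sample(2:6, 1)
      aa <- matrix(runif(2 * na, 0, 30), na)
      bb <- matrix(runif(2 * nb, 0, 30), nb)
      md <- 12
      got <- match_neurons(aa, bb, max_dist = md)
      want <- oracle_match(aa, bb, md)
      expect_equal(nrow(got$matches), nrow(want$pairs))
      expect_equal(got$total_dist,
                   sum(sqrt(rowSums((aa[want$pairs[, 1], , drop = FALSE] -
                                       bb[want$pairs[, 2], , drop = FALSE])^2))),
                   tolerance = 1e-9)
    }
  })
})
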