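# Normalization: z-scoring, bleach screening, slow baseline, dF/F0,
# downsampling.

test_that("z-scoring applies (raw - mu)/sigma with baseline moments", {
  # baseline alternates 3/7: mean 5, population sd 2; later sample 9 -> z = 2
  base <- rep(c(3, 7), 40)
  tm <- trace_matrix(rbind(c(base, 9)), sample_rate = 1)
  z <- zscore_traces(tm, baseline_window = c(0, 80))
  expect_equal(unname(z$mu), 5)
  expect_equal(unname(z$sigma), 2)
  expect_equal(unname(z$values[1, 81]), 2)
  # the baseline segment itself has mean 0 and (population) sd 1
  zb <- z$values[1, 1:80]
  expect_equal(mean(zb), 0)
  expect_equal(ingestphase:::sd_pop(zb), 1)
})

test_that("z-scoring equals a two-pass oracle on random traces", {
  withr::with_seed(42, {
    for (k in 1:50) {
      n <- sample(50:200, 1)
      vals <- matrix(rnorm(3 * n, mean = runif(1, -5, 5),
                           sd = runif(1, 0.5, 3)), nrow = 3)
      tm <- trace_matrix(vals, sample_rate = 2)
      bw <- c(0, n / 4)
      z <- zscore_traces(tm, bw)
      # samples whose (left-edge) time lies in [0, bw[2])
      idx <- which((seq_len(n) - 1) / 2 < bw[2])
      for (i in 1:3) {
        mu <- sum(vals[i, idx]) / length(idx)
        sg <- sqrt(sum((vals[i, idx] - mu)^2) / length(idx))
        expect_equal(z$values[i, ], (vals[i, ] - mu) / sg)
      }
    }
  })
})

test_that("z-scoring is invariant to positive affine rescaling of the raw trace", {
  withr::with_seed(7, {
    x <- rnorm(400, 10, 2)
    tm1 <- trace_matrix(rbind(x), 2)
    tm2 <- trace_matrix(rbind(3.7 * x + 11), 2)
    z1 <- zscore_traces(tm1, c(0, 100))
    z2 <- zscore_traces(tm2, c(0, 100))
    expect_equal(z1$values, z2$values, tolerance = 1e-10)
  })
})

test_that("zero-variance baselines are flagged degenerate unless constant", {
  vals <- rbind(c(rep(1, 50), rep(1, 50)),   # constant: kept, z == 0
                c(rep(1, 50), rnorm(50)))    # flat baseline then signal: out
  tm <- trace_matrix(vals, 1)
  z <- zscore_traces(tm, c(0, 50))
  expect_equal(nrow(z$values), 1)
  expect_true(all(z$values[1, ] == 0))
  expect_equal(z$excluded$neuron_id, "n2")
})

test_that("bleach screening excludes exponentials and keeps flat noise", {
  withr::with_seed(3, {
    t_s <- (0:4799) / 8
    bleach <- 20 * exp(-t_s / 120) + 10 + rnorm(4800, 0, 0.5)
    flat <- 10 + rnorm(4800, 0, 0.5)
    tm <- trace_matrix(rbind(bleach, flat), 8)
    sc <- screen_bleaching(tm, c(0, 600))
    expect_equal(sc$excluded, "n1")
    expect_equal(sc$kept, "n2")
    # idempotent: re-screening the kept neuron excludes nothing
    tm2 <- trace_matrix(tm$values[2, , drop = FALSE], 8, "n2")
    expect_length(screen_bleaching(tm2, c(0, 600))$excluded, 0)
  })
})

test_that("bleach screening recovers generator labels in a mixed population", {
  s <- make_infusion_session(n_neurons = 20, seed = 8,
                             noise = list(n_bleach = 4))
  sc <- screen_bleaching(s$traces, c(0, 600))
  expect_setequal(sc$excluded, attr(s$traces, "bleach_ids"))
})

test_that("the slow-baseline filter preserves DC and kills fast components", {
  fs <- 8
  const <- rep(3.5, fs * 300)
  out <- baseline_fluorescence(const, sample_rate = fs)
  expect_equal(out, const, tolerance = 1e-6)
  # 20-s period sinusoid sits in the stopband: >= 20 dB attenuation
  t_s <- (0:(fs * 600 - 1)) / fs
  sine <- sin(2 * pi * t_s / 20)
  filt <- baseline_fluorescence(sine, sample_rate = fs)
  mid <- seq(fs * 60, fs * 540)
  gain <- max(abs(filt[mid])) / 1
  expect_lt(20 * log10(gain), -20)
})

test_that("the filter's measured frequency response matches an FFT oracle", {
  fs <- 8
  t_s <- (0:(fs * 1200 - 1)) / fs
  mid <- seq(fs * 300, fs * 900)
  for (period_s in c(600, 120, 30)) {
    sine <- sin(2 * pi * t_s / period_s)
    filt <- baseline_fluorescence(sine, sample_rate = fs)
    # measured gain via the dominant FFT bin over the middle section
    gain_meas <- max(abs(filt[mid])) / max(abs(sine[mid]))
    # oracle: squared Butterworth magnitude (filtfilt = two passes) from the
    # transfer function evaluated on the unit circle
    bf <- signal::butter(2, (1 / 60) / (fs / 2), type = "low")
    w <- 2 * pi * (1 / period_s) / fs
    h <- sum(bf$b * exp(-1i * w * (seq_along(bf$b) - 1))) /
      sum(bf$a * exp(-1i * w * (seq_along(bf$a) - 1)))
    gain_oracle <- Mod(h)^2
    expect_equal(gain_meas, gain_oracle, tolerance = 0.05)
  }
})

test_that("lowpass and z-score commute up to filter linearity", {
  withr::with_seed(11, {
    fs <- 4
    x <- 10 + cumsum(rnorm(fs * 600, 0, 0.1)) + rnorm(fs * 600)
    tm <- trace_matrix(rbind(x), fs)
    z <- zscore_traces(tm, c(0, 300))
    a <- baseline_fluorescence(z$values[1, ], sample_rate = fs)
    b <- (baseline_fluorescence(x, sample_rate = fs) - z$mu[1]) / z$sigma[1]
    expect_equal(a, b, tolerance = 1e-6)
  })
})

test_that("isosbestic dF/F0 is exact on exact linear channels", {
  withr::with_seed(5, {
    ref <- 50 + cumsum(rnorm(2000, 0, 0.05))
    sig <- 2 * ref + 1
    ph <- photometry_signal(sig, ref, 2)
    dff <- dff_isosbestic(ph, c(0, 600))
    expect_equal(unname(dff$coefficients["slope"]), 2, tolerance = 1e-8)
    expect_equal(max(abs(dff$values)), 0, tolerance = 1e-10)
    # transient of magnitude d on the signal channel only -> d / F0(t)
    sig2 <- sig
    sig2[1500] <- sig2[1500] + 7
    dff2 <- dff_isosbestic(photometry_signal(sig2, ref, 2), c(0, 600))
    f0 <- 2 * ref[1500] + 1
    expect_equal(dff2$values[1500], 7 / f0, tolerance = 1e-10)
  })
})

test_that("dF/F0 is invariant to a common gain on both channels", {
  withr::with_seed(6, {
    ref <- 50 + cumsum(rnorm(2000, 0, 0.05))
    sig <- 1.5 * ref + 3 + rnorm(2000, 0, 0.01)
    d1 <- dff_isosbestic(photometry_signal(sig, ref, 2), c(0, 500))
    d2 <- dff_isosbestic(photometry_signal(4 * sig, 4 * ref, 2), c(0, 500))
    expect_equal(d1$values, d2$values, tolerance = 1e-8)
  })
})

test_that("a constant reference channel is rejected", {
  ph <- photometry_signal(rnorm(100, 10), rep(5, 100), 1)
  expect_error(dff_isosbestic(ph, c(0, 50)), "constant")
})

test_that("downsampling is an exact block average", {
  x <- rnorm(80)
  y <- downsample_series(x, 4, native_rate = 8)
  expect_length(y, 40)
  oracle <- colMeans(matrix(x, nrow = 2))
  expect_equal(y, oracle)
  expect_equal(downsample_series(rep(2.5, 100), 1, native_rate = 10),
               rep(2.5, 10))
  expect_error(downsample_series(x, 16, native_rate = 8), "<=")
  # non-integer ratio: windowed-average oracle
  x2 <- rnorm(101)
  y2 <- downsample_series(x2, 3, native_rate = 7)
  t_s <- (0:100) / 7
  n_out <- floor(101 * 3 / 7)
  oracle2 <- vapply(0:(n_out - 1), function(b)
    mean(x2[floor(t_s * 3) == b]), numeric(1))
  expect_equal(y2, oracle2)
})
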