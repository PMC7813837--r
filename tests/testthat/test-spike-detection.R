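test_that("high-pass rejects DC and preserves the spike band", {
  fs <- 1e4
  t <- (0:199999) / fs
  # DC rejection
  y <- highpass_filter(rep(5, 2e5), 1, fs)
  expect_lt(max(abs(y[5e4:15e4])), 0.05)
  # passband fidelity at 100 Hz
  y100 <- highpass_filter(sin(2 * pi * 100 * t), 1, fs)
  expect_lt(abs(max(abs(y100[5e4:15e4])) - 1), 0.01)
  # stopband attenuation matches the squared first-order response
  y01 <- highpass_filter(sin(2 * pi * 0.1 * t), 1, fs)
  analytic <- (0.1 / 1)^2 / (1 + (0.1 / 1)^2)   # forward+backward pass
  expect_equal(max(abs(y01[5e4:15e4])), analytic, tolerance = 0.1)
  expect_error(highpass_filter(t, 6000, fs), "Nyquist")
})

test_that("binomial smoothing kernel and cutoff behave as designed", {
  # kernel definition: one pass of (1, 2, 1)/4
  imp <- c(rep(0, 10), 1, rep(0, 10))
  expect_equal(binomial_smooth(imp, n_passes = 1)[10:12],
               c(0.25, 0.5, 0.25))
  # exact unit DC gain
  expect_equal(binomial_smooth(rep(2.5, 500), 100, 1e4), rep(2.5, 500),
               tolerance = 1e-12)
  # pass count: brute-force search over the closed-form response
  fs <- 1e4
  resp3db <- function(n) (fs / pi) * acos(2^(-1 / (4 * n)))
  n_oracle <- 1
  while (resp3db(n_oracle) > 100) n_oracle <- n_oracle + 1
  expect_identical(binomial_passes(100, fs), as.integer(n_oracle))
  # measured -3 dB point of the implemented filter within 2% of 100 Hz
  t <- (0:199999) / fs
  amp <- function(f) {
    y <- binomial_smooth(sin(2 * pi * f * t), 100, fs)
    max(abs(y[5e4:15e4]))
  }
  f3 <- stats::uniroot(function(f) amp(f) - 1 / sqrt(2),
                       c(80, 120), tol = 0.1)$root
  expect_lt(abs(f3 - 100) / 100, 0.02)
})

test_that("background SD estimation is robust to sparse spikes", {
  fs <- 1e4
  dc <- detection_config()
  noise <- device_noise_trace(1e6, seed = 21)
  fn <- filter_trace(noise, dc, fs)
  est <- estimate_background_sd(fn, dc, fs)
  expect_lt(abs(est$sd_current - stats::sd(fn)) / stats::sd(fn), 0.02)
  # all-zero trace
  expect_equal(estimate_background_sd(rep(0, 2e4), dc, fs),
               list(sd_current = 0, sd_derivative = 0))
  expect_error(estimate_background_sd(rep(0, 100), dc, fs), "1 s")
  # inject 10 large spikes (<1% of samples); estimates barely move
  sch <- do.call(rbind, lapply(seq(5, 95, by = 10), function(on)
    spike_row(on, 40, 7.33)))
  spikes <- render_clean_traces(sch, 0L, 100, sample_rate = fs,
                                integrate = TRUE)
  fboth <- filter_trace(noise + spikes$traces[1, ], dc, fs)
  est2 <- estimate_background_sd(fboth, dc, fs)
  expect_lt(abs(est2$sd_current - est$sd_current) / est$sd_current, 0.03)
  expect_lt(abs(est2$sd_derivative - est$sd_derivative) /
              est$sd_derivative, 0.03)
})

test_that("detection is deterministic, localized, and empty on silence", {
  fs <- 1e4
  dc <- detection_config()
  expect_identical(nrow(detect_spikes(rep(0, 5e4), dc, fs)), 0L)
  expect_error(detect_spikes(c(rep(0, 5e4), NA), dc, fs), "NA")
  # noise-free rendered spikes: peak localized within one sample
  sch <- rbind(spike_row(3, 14.3, 7.33), spike_row(7, 20, 9),
               spike_row(12, 8, 5))
  rec <- render_clean_traces(sch, 0L, 20, sample_rate = fs,
                             integrate = TRUE)
  ev <- detect_spikes(rec$traces[1, ], dc, fs)
  expect_identical(nrow(ev), 3L)
  expect_true(all(abs(ev$t_peak_s - true_peak_time(sch)) <= 1 / fs + 1e-9))
  expect_true(all(ev$t_start_s < ev$t_peak_s & ev$t_peak_s < ev$t_end_s))
  # identical input, identical output
  expect_identical(ev, detect_spikes(rec$traces[1, ], dc, fs))
})

test_that("lowering the threshold never loses events", {
  fs <- 1e4
  sch <- rbind(spike_row(2, 14.3, 7.33), spike_row(5, 6, 5),
               spike_row(8, 25, 9))
  rec <- render_clean_traces(sch, 0L, 10, sample_rate = fs,
                             integrate = TRUE)
  rec <- add_noise(rec, noise_model(drift_amplitude = 0), seed = 13)
  f <- filter_trace(rec$traces[1, ], detection_config(), fs)
  counts <- vapply(c(8, 6, 5, 4, 3), function(k) {
    nrow(detect_spikes(f, detection_config(threshold_multiple = k), fs))
  }, integer(1))
  expect_true(all(diff(counts) >= 0))
})

test_that("a canonical spike in device noise is reliably found and timed", {
  fs <- 1e4
  dc <- detection_config()
  sch <- spike_row(10, 11.9, 7.33)       # peak current 1.3 pA
  tpk <- true_peak_time(sch)
  clean <- render_clean_traces(sch, 0L, 20, sample_rate = fs,
                               integrate = TRUE)
  n_one <- 0; dts <- c()
  for (s in 1:50) {
    rec <- add_noise(clean, noise_model(), seed = s)
    f <- filter_trace(rec$traces[1, ], dc, fs)
    ev <- detect_spikes(f, dc, fs)
    if (nrow(ev) == 1) {
      n_one <- n_one + 1
      dts <- c(dts, abs(ev$t_peak_s - tpk))
    }
  }
  expect_gte(n_one / 50, 0.95)
  expect_lt(stats::median(dts), 0.002)   # median timing error < 2 ms
  expect_lt(max(dts), 0.01)              # worst-case within the smoothing scale
})

test_that("false positives on pure noise sit within the surrogate bound", {
  fs <- 1e4
  dc <- detection_config()
  noise <- device_noise_trace(3e5, seed = 31)        # 30 s
  f <- filter_trace(noise, dc, fs)
  n_obs <- nrow(detect_spikes(f, dc, fs))
  # time-shuffled surrogates share the marginal distribution but no
  # temporal structure; re-run the identical chain on each
  set.seed(77)
  n_surr <- vapply(1:20, function(i) {
    sh <- sample(noise)
    nrow(detect_spikes(filter_trace(sh, dc, fs), dc, fs))
  }, integer(1))
  expect_lte(n_obs, stats::quantile(n_surr, 0.99) + 1)
})

test_that("the filter chain reduces noise by the bandwidth ratio", {
  fs <- 1e4
  x <- device_noise_trace(1e6, seed = 41)
  f <- filter_trace(x, detection_config(), fs)
  expected <- 0.9 * sqrt(100 / 4400)
  expect_lt(abs(stats::sd(f) - expected) / expected, 0.15)
})
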