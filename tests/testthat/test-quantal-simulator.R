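test_that("waveform peak obeys amplitude and time-dilation scaling exactly", {
  m <- spike_waveform_model()
  p1 <- waveform_peak(14.3, 7.33, m)
  expect_identical(waveform_peak(28.6, 7.33, m), 2 * p1)
  expect_equal(waveform_peak(14.3, 14.66, m), p1 / 2, tolerance = 1e-12)
  expect_error(waveform_peak(-1, 5, m), "positive")
  expect_error(spike_waveform_model(1.3), "in \\(0, 1\\)")
})

test_that("waveform peak and width match dense numerical evaluation", {
  m <- spike_waveform_model()
  t_ms <- seq(0, 200, by = 1e-3)          # 1 us grid
  w <- waveform_eval(t_ms, 14.3, 7.33, m)
  expect_equal(waveform_peak(14.3, 7.33, m), max(w), tolerance = 1e-8)
  half <- max(w) / 2
  fwhm <- diff(range(t_ms[w >= half]))
  expect_equal(fwhm, 7.33, tolerance = 1e-3)
  expect_equal(sum(w) * 1e-3, 14.3, tolerance = 1e-4)  # unit charge
})

test_that("vesicle charges follow the truncated cube-law population", {
  # zero variance: all charges equal c * d^3
  q <- sample_vesicle_charges(vesicle_population(2, 0, 3), 5, seed = 1)
  expect_equal(q, rep(3 * 8, 5))
  expect_error(sample_vesicle_charges(vesicle_population(1, 0.1, 1), 0),
               "positive integer")
  expect_error(vesicle_population(-1, 0.1, 1), "invalid")

  # seed determinism
  pop <- vesicle_population(1, 0.2, 1)
  expect_identical(sample_vesicle_charges(pop, 100, seed = 7),
                   sample_vesicle_charges(pop, 100, seed = 7))

  # quadrature oracle: E[Q] = E[phi^3] for the positive-truncated normal
  mu <- 1; s <- 0.2
  e3 <- stats::integrate(function(x) x^3 * stats::dnorm(x, mu, s),
                         0, Inf)$value / stats::pnorm(mu / s)
  qs <- sample_vesicle_charges(pop, 1e6, seed = 2)
  expect_lt(abs(mean(qs) - e3), 3 * stats::sd(qs) / sqrt(1e6))
})

test_that("cube-root calibrated population reproduces the target scale", {
  pop <- population_from_cuberoot(0.40, 0.08)
  q <- sample_vesicle_charges(pop, 1e5, seed = 3)
  amol13 <- (q / pop$charge_coefficient)^(1 / 3)
  expect_lt(abs(mean(amol13) - 0.40), 3 * 0.08 / sqrt(1e5))
  # charge-mean calibration hits its target through the third moment
  pop2 <- population_from_charge(14.3, 0.08)
  q2 <- sample_vesicle_charges(pop2, 2e5, seed = 4)
  expect_lt(abs(mean(q2) - 14.3), 3 * stats::sd(q2) / sqrt(2e5))
})

test_that("cube-root of sampled quantal size is Gaussian to low skewness", {
  pop <- population_from_cuberoot(0.4, 0.1)   # CV 0.25, upper edge
  q <- sample_vesicle_charges(pop, 1e5, seed = 5)
  x <- q^(1 / 3)
  skew <- mean((x - mean(x))^3) / stats::sd(x)^3
  expect_lt(abs(skew), 0.05)
})

test_that("event schedules follow the stimulated Poisson law", {
  pop <- population_from_charge(14.3, 0.08)
  quiet <- cell_model("c1", 0L, event_rate = 0, vesicles = pop)
  expect_identical(nrow(generate_event_schedule(list(quiet), 840,
                                                seed = 1)), 0L)
  expect_identical(nrow(generate_event_schedule(list(), 840, seed = 1)), 0L)

  # Poisson(100): one cell, rate 1/s, a single 100 s window
  cell <- cell_model("c1", 0L, event_rate = 1, vesicles = pop)
  counts <- vapply(1:1000, function(s) {
    nrow(generate_event_schedule(list(cell), 200, list(c(50, 150)),
                                 seed = s))
  }, integer(1))
  expect_lt(abs(mean(counts) - 100), 3 * 10 / sqrt(1000))
  # chi-square goodness of fit against Poisson(100), alpha = 0.01
  brk <- c(-Inf, stats::qpois(seq(0.1, 0.9, by = 0.1), 100), Inf)
  obs <- table(cut(counts, brk))
  pr <- diff(stats::ppois(c(-Inf, stats::qpois(seq(0.1, 0.9, by = 0.1),
                                               100), Inf), 100))
  expect_gt(stats::chisq.test(as.vector(obs), p = pr,
                              rescale.p = TRUE)$p.value, 0.01)
})

test_that("a control-scale cohort produces the expected event total", {
  # 16 cells calibrated for 477 events over the stimulated epochs
  stim <- default_stimulation_windows(840)
  stim_time <- sum(vapply(stim, function(w) w[2] - w[1], numeric(1)))
  rate <- 477 / (16 * stim_time)
  cells <- make_cohort(16, rate, seed = 9)
  totals <- vapply(1:300, function(s) {
    nrow(generate_event_schedule(cells, 840, stim, seed = s))
  }, integer(1))
  # mean within 3 standard errors of 477
  expect_lt(abs(mean(totals) - 477), 3 * stats::sd(totals) / sqrt(300))
  # every onset inside a stimulation window
  sch <- generate_event_schedule(cells, 840, stim, seed = 1)
  inside <- vapply(sch$onset_s, function(t)
    any(vapply(stim, function(w) t >= w[1] && t <= w[2], logical(1))),
    logical(1))
  expect_true(all(inside))
})

test_that("schedules are bit-identical under a fixed seed", {
  cells <- make_cohort(4, 0.05, seed = 2)
  s1 <- generate_event_schedule(cells, 120, seed = 42)
  s2 <- generate_event_schedule(cells, 120, seed = 42)
  expect_identical(s1, s2)
})

test_that("rendered traces conserve charge and superpose", {
  expect_equal(
    render_clean_traces(spike_row(1, 10, 7)[0, ], 0L, 2)$traces,
    matrix(0, 1, 2e4))
  # single event: trapezoidal integral within 0.01 fC of 10
  sch <- spike_row(0.3, 10, 7.33)
  rec <- render_clean_traces(sch, 0L, 2, sample_rate = 1e4)
  q_trap <- sum(rec$traces[1, ]) / 1e4 * 1e3     # pA / Hz -> fC
  expect_lt(abs(q_trap - 10), 0.01)
  # window-averaged (integrate-and-reset) rendering is charge-exact
  rec_i <- render_clean_traces(sch, 0L, 2, sample_rate = 1e4,
                               integrate = TRUE)
  expect_lt(abs(sum(rec_i$traces[1, ]) / 1e4 * 1e3 - 10), 1e-3)
  # superposition: overlapping events add pointwise
  a <- spike_row(0.30, 10, 7.33)
  b <- spike_row(0.31, 6, 5)
  both <- rbind(a, b)
  r_ab <- render_clean_traces(both, 0L, 2)
  r_a <- render_clean_traces(a, 0L, 2)
  r_b <- render_clean_traces(b, 0L, 2)
  expect_equal(r_ab$traces, r_a$traces + r_b$traces, tolerance = 1e-12)
  # events outside the rendered channel set are an error
  expect_error(render_clean_traces(a, 3L, 2), "outside")
})
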