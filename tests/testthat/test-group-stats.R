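ev_row <- function(cell, q, channel = 0L) {
  data.frame(channel = channel, cell_id = cell, i_max_pA = q / 10,
             t_half_ms = 7, q_fC = q,
             n_molecules = molecules_from_charge(q),
             q_amol_cuberoot = (molecules_from_charge(q) /
                                  physical_constants()$avogadro /
                                  1e-18)^(1 / 3))
}

test_that("cell medians use the conventional mean-of-middle-two rule", {
  ev <- rbind(ev_row("a", 1), ev_row("a", 2), ev_row("a", 9))
  s <- summarize_cells(ev)
  expect_equal(s$median_q_fC, 2)
  expect_equal(s$n_spikes, 3L)
  ev2 <- rbind(ev_row("b", 1), ev_row("b", 3))
  expect_equal(summarize_cells(ev2)$median_q_fC, 2)
  # medians lie inside the per-cell range
  expect_true(s$median_q_fC >= 1 && s$median_q_fC <= 9)
})

test_that("unmapped channels are reported by name", {
  ev <- ev_row("x", 5, channel = 7L)
  ev$cell_id <- NULL
  expect_error(summarize_cells(ev, data.frame(channel = 0L, cell_id = "a")),
               "7")
})

test_that("group means of cell medians match a brute-force oracle", {
  # 63 cells with heavy-tailed activity (1..40 spikes per cell)
  set.seed(8)
  cells <- sprintf("c%02d", 1:63)
  ev <- do.call(rbind, lapply(seq_along(cells), function(i) {
    n <- 1 + stats::rpois(1, stats::rexp(1, 1 / 8))
    do.call(rbind, lapply(stats::rlnorm(n, log(14), 0.5),
                          function(q) ev_row(cells[i], q, channel = i)))
  }))
  s <- summarize_cells(ev)
  # oracle: per-cell sort and explicit middle element(s)
  oracle <- vapply(cells, function(cl) {
    v <- sort(ev$q_fC[ev$cell_id == cl])
    n <- length(v)
    if (n %% 2 == 1) v[(n + 1) / 2] else (v[n / 2] + v[n / 2 + 1]) / 2
  }, numeric(1))
  expect_equal(mean(s$median_q_fC[match(cells, s$cell_id)]), mean(oracle),
               tolerance = 1e-12)
})

test_that("duplicating every spike of one cell changes no group statistic", {
  set.seed(9)
  mk <- function(ids, mu) do.call(rbind, lapply(seq_along(ids), function(i)
    do.call(rbind, lapply(stats::rlnorm(9, log(mu), 0.4),
                          function(q) ev_row(ids[i], q, channel = i)))))
  ctrl <- mk(sprintf("c%d", 1:6), 14)
  trt <- mk(sprintf("t%d", 1:6), 26)
  r1 <- group_report(ctrl, trt)
  ctrl_dup <- rbind(ctrl, ctrl[ctrl$cell_id == "c3", ])
  r2 <- group_report(ctrl_dup, trt)
  for (ch in names(r1$characteristics)) {
    expect_equal(r1$characteristics[[ch]]$mean_control,
                 r2$characteristics[[ch]]$mean_control, tolerance = 1e-12)
    expect_equal(r1$characteristics[[ch]]$p,
                 r2$characteristics[[ch]]$p, tolerance = 1e-12)
  }
})

test_that("percent change reproduces the reported group contrasts", {
  expect_identical(percent_change(14.3, 26.6), 86)
  expect_identical(percent_change(1.30, 1.75), 35)
  expect_identical(percent_change(7.33, 9.15), 25)
  expect_identical(percent_change(5, 5), 0)
  expect_error(percent_change(0, 1), "nonzero")
  # inverse composition, unrounded
  p1 <- percent_change(14.3, 26.6, rounded = FALSE)
  p2 <- percent_change(26.6, 14.3, rounded = FALSE)
  expect_equal((1 + p1 / 100) * (1 + p2 / 100), 1, tolerance = 1e-12)
})

test_that("the pooled t test matches the closed-form oracle", {
  a <- c(1, 2, 3); b <- c(4, 5, 6)
  res <- two_group_test(a, b)
  # hand-computed pooled-variance Student's t
  sp2 <- (2 * stats::var(a) + 2 * stats::var(b)) / 4
  t_hand <- (mean(a) - mean(b)) / sqrt(sp2 * (1 / 3 + 1 / 3))
  expect_equal(res$t, t_hand, tolerance = 1e-12)
  expect_equal(res$t, -3.674, tolerance = 1e-3)
  expect_equal(res$df, 4)
  expect_equal(res$p, 2 * stats::pt(t_hand, 4), tolerance = 1e-12)
  expect_equal(res$p, 0.0214, tolerance = 1e-2)
  # degenerate identical groups
  same <- two_group_test(c(2, 2), c(2, 2))
  expect_equal(same$t, 0)
  expect_equal(same$p, 1)
  expect_error(two_group_test(1, c(1, 2)), "at least 2")
  # Welch equals pooled for equal sizes and variances
  x <- c(1, 2, 3, 4); y <- c(11, 12, 13, 14)
  expect_equal(two_group_test(x, y, "welch")$t,
               two_group_test(x, y, "pooled")$t, tolerance = 1e-12)
  expect_equal(two_group_test(x, y, "welch")$df,
               two_group_test(x, y, "pooled")$df, tolerance = 1e-12)
})

test_that("cube-root Gaussian fitting estimates and screens distributions", {
  set.seed(10)
  x <- stats::rnorm(477, 0.40, 0.08)
  fit <- fit_cuberoot_gaussian(x)
  expect_lt(abs(fit$mean - 0.40), 3 * 0.08 / sqrt(477))
  expect_lt(abs(fit$sd - 0.08), 3 * 0.08 / sqrt(477))
  expect_warning(f0 <- fit_cuberoot_gaussian(rep(1, 10)), "degenerate")
  expect_equal(f0$sd, 0)
  expect_error(fit_cuberoot_gaussian(1:5), "at least 8")
  # strongly log-normal data are rejected
  y <- stats::rlnorm(1e4, 0, 1)
  expect_lt(fit_cuberoot_gaussian(y)$normality_p, 0.01)
})

test_that("cohort-scale reports reproduce the configured contrasts", {
  # ground-truth events for 16 control and 63 treated cells at the
  # reference rates; the report must recover the configured percent
  # changes within Monte-Carlo tolerance (10 percentage points)
  win <- default_stimulation_windows(840)
  cc <- make_cohort(16, 477 / (16 * 720),
                    vesicles = population_from_charge(14.3, 0.08),
                    halfwidth_mean = 7.33, seed = 71)
  tc <- make_cohort(63, 3534 / (63 * 720),
                    vesicles = population_from_charge(26.6, 0.11),
                    halfwidth_mean = 9.15, n_channels = 512L, seed = 72)
  sc <- schedule_as_events(generate_event_schedule(cc, 840, win, seed = 73))
  st <- schedule_as_events(generate_event_schedule(tc, 840, win, seed = 74))
  r <- group_report(sc, st)
  expect_lt(abs(r$characteristics$q$percent_change - 86), 10)
  expect_lt(abs(r$characteristics$t_half$percent_change - 25), 10)
  expect_lt(abs(r$characteristics$i_max$percent_change -
                  percent_change(waveform_peak(14.3, 7.33),
                                 waveform_peak(26.6, 9.15))), 10)
  expect_lt(r$characteristics$q$p, 0.001)
  expect_identical(r$n_control, 16L)
  expect_identical(r$n_treated, 63L)
})

test_that("box statistics use type-7 quartiles with whiskers at the extremes", {
  b <- boxplot_stats(1:100)
  expect_equal(b$q1, 25.75)
  expect_equal(b$median, 50.5)
  expect_equal(b$q3, 75.25)
  expect_equal(b$min, 1)
  expect_equal(b$max, 100)
})

test_that("identical groups give null contrasts and a full report structure", {
  set.seed(11)
  ev <- do.call(rbind, lapply(1:6, function(i)
    do.call(rbind, lapply(stats::rlnorm(9, log(14), 0.4),
                          function(q) ev_row(sprintf("c%d", i), q,
                                             channel = i)))))
  r <- group_report(ev, ev)
  for (ch in names(r$characteristics)) {
    expect_identical(r$characteristics[[ch]]$percent_change, 0)
    expect_equal(r$characteristics[[ch]]$p, 1)
    # histogram counts sum to the spike counts
    expect_identical(sum(r$characteristics[[ch]]$hist$counts_control),
                     nrow(ev))
  }
  expect_identical(r$n_control, 6L)
  # JSON round trip is well formed
  path <- tempfile(fileext = ".json")
  write_group_report(r, path)
  back <- jsonlite::read_json(path)
  expect_equal(back$characteristics$q$percent_change, 0)
})
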