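#' Vesicle population model
#'
#' Secretory vesicles carry a Gaussian-distributed diameter `phi`; the
#' quantal charge released on full fusion scales with vesicle volume,
#' `Q = charge_coefficient * phi^3`. Working in diameter units of
#' attomole^(1/3) of releasable analyte makes `charge_coefficient` the
#' oxidation charge of one attomole (about 193 fC for a two-electron
#' analyte), so `Q^(1/3)` expressed in attomole^(1/3) is Gaussian with the
#' population's diameter mean and SD.
#'
#' @param diameter_mean Mean vesicle diameter (arbitrary units, > 0).
#' @param diameter_sd SD of vesicle diameter (same units, >= 0).
#' @param charge_coefficient Charge per unit diameter cubed (fC / a.u.^3).
#' @return An object of class `vesicle_population`.
#' @export
vesicle_population <- function(diameter_mean, diameter_sd,
                               charge_coefficient) {
  if (!is.numeric(diameter_mean) || diameter_mean <= 0 ||
      !is.numeric(diameter_sd) || diameter_sd < 0 ||
      !is.numeric(charge_coefficient) || charge_coefficient <= 0) {
    stop("invalid vesicle population parameters")
  }
  structure(list(diameter_mean = diameter_mean, diameter_sd = diameter_sd,
                 charge_coefficient = charge_coefficient),
            class = "vesicle_population")
}

#' Calibrate a vesicle population from cube-root quantal size statistics
#'
#' Builds a population whose sampled `Q^(1/3)` (in attomole^(1/3)) is
#' Gaussian with the given mean and SD — the scale on which amperometric
#' quantal-size histograms are Gaussian.
#'
#' @param cuberoot_mean,cuberoot_sd Mean and SD of quantal size^(1/3) in
#'   attomole^(1/3).
#' @param constants Physical constants, see [physical_constants()].
#' @return A `vesicle_population`.
#' @export
population_from_cuberoot <- function(cuberoot_mean, cuberoot_sd,
                                     constants = physical_constants()) {
  vesicle_population(cuberoot_mean, cuberoot_sd,
                     .charge_per_attomole_fC(constants))
}

#' Calibrate a vesicle population from a target mean quantal charge
#'
#' Solves the diameter mean so that the population's expected charge
#' `E[Q] = c * (mu^3 + 3 mu sigma^2)` (Gaussian third moment; diameter
#' truncation at zero is negligible at the CVs used here) matches
#' `q_mean_fC`, holding the cube-root SD fixed.
#'
#' @param q_mean_fC Target mean quantal charge (fC).
#' @param cuberoot_sd SD of quantal size^(1/3) in attomole^(1/3).
#' @inheritParams population_from_cuberoot
#' @return A `vesicle_population`.
#' @export
population_from_charge <- function(q_mean_fC, cuberoot_sd,
                                   constants = physical_constants()) {
  stopifnot(q_mean_fC > 0, cuberoot_sd >= 0)
  cc <- .charge_per_attomole_fC(constants)
  target <- q_mean_fC / cc
  mu <- stats::uniroot(
    function(m) m^3 + 3 * m * cuberoot_sd^2 - target,
    c(1e-9, target^(1/3) + 3 * cuberoot_sd), tol = 1e-12
  )$root
  vesicle_population(mu, cuberoot_sd, cc)
}

#' Sample quantal charges from a vesicle population
#'
#' Diameters are drawn from the Gaussian truncated to positive values (by
#' rejection) and cubed: `Q_i = c * phi_i^3`.
#'
#' @param pop A [vesicle_population()].
#' @param n Number of charges to draw (>= 1).
#' @param seed Optional integer seed; a given seed reproduces the draw.
#' @return Numeric vector of `n` charges in fC.
#' @export
sample_vesicle_charges <- function(pop, n, seed = NULL) {
  stopifnot(inherits(pop, "vesicle_population"))
  if (!is.numeric(n) || length(n) != 1 || n < 1 || n != round(n)) {
    stop("`n` must be a positive integer")
  }
  if (!is.null(seed)) set.seed(seed)
  phi <- .rnorm_truncated_pos(n, pop$diameter_mean, pop$diameter_sd)
  pop$charge_coefficient * phi^3
}

# positive-truncated normal by rejection; exact and cheap when mean/sd >~ 3
.rnorm_truncated_pos <- function(n, mean, sd) {
  if (sd == 0) return(rep(mean, n))
  out <- stats::rnorm(n, mean, sd)
  bad <- which(out <= 0)
  while (length(bad)) {
    out[bad] <- stats::rnorm(length(bad), mean, sd)
    bad <- bad[out[bad] <= 0]
  }
  out
}

#' Single-cell release model
#'
#' One cell sits on one electrode and releases vesicles as a homogeneous
#' Poisson process (at `event_rate`) during stimulation windows; each event
#' draws its charge from the cell's vesicle population and its half-width
#' from a log-normal with the given mean and coefficient of variation.
#'
#' @param cell_id Identifier.
#' @param channel 0-based electrode channel index.
#' @param event_rate Events per second during stimulation (>= 0).
#' @param halfwidth_mean Mean spike half-width (ms, > 0).
#' @param halfwidth_cv Coefficient of variation of half-width, in [0, 1).
#' @param vesicles A [vesicle_population()].
#' @return An object of class `cell_model`.
#' @export
cell_model <- function(cell_id, channel, event_rate,
                       halfwidth_mean = 7.33, halfwidth_cv = 0.4,
                       vesicles = population_from_charge(14.3, 0.08)) {
  if (event_rate < 0) stop("`event_rate` must be >= 0")
  if (halfwidth_mean <= 0) stop("`halfwidth_mean` must be > 0")
  if (halfwidth_cv < 0 || halfwidth_cv >= 1) {
    stop("`halfwidth_cv` must be in [0, 1)")
  }
  structure(list(cell_id = cell_id, channel = as.integer(channel),
                 event_rate = event_rate, halfwidth_mean = halfwidth_mean,
                 halfwidth_cv = halfwidth_cv, vesicles = vesicles),
            class = "cell_model")
}

#' Build a cohort of cells on distinct electrodes
#'
#' Cells are placed on distinct channels drawn uniformly at random from the
#' array (one cell per electrode).
#'
#' @param n_cells Number of cells.
#' @param event_rate Per-cell stimulated event rate (events / s).
#' @param vesicles Shared vesicle population.
#' @param halfwidth_mean,halfwidth_cv Half-width distribution parameters.
#' @param n_channels Number of electrodes available (default 1024).
#' @param prefix Cell id prefix.
#' @param seed Optional seed for channel placement.
#' @return List of [cell_model()]s.
#' @export
make_cohort <- function(n_cells, event_rate,
                        vesicles = population_from_charge(14.3, 0.08),
                        halfwidth_mean = 7.33, halfwidth_cv = 0.4,
                        n_channels = 1024L, prefix = "cell",
                        seed = NULL) {
  stopifnot(n_cells >= 1, n_cells <= n_channels)
  if (!is.null(seed)) set.seed(seed)
  chans <- sample.int(n_channels, n_cells) - 1L
  lapply(seq_len(n_cells), function(i) {
    cell_model(sprintf("%s_%02d", prefix, i), chans[i], event_rate,
               halfwidth_mean, halfwidth_cv, vesicles)
  })
}

# merge overlapping/abutting stimulation windows, clip to [0, duration]
.merge_windows <- function(windows, duration) {
  if (length(windows) == 0) return(matrix(numeric(0), ncol = 2))
  w <- do.call(rbind, lapply(windows, function(x) c(x[1], x[2])))
  w[, 1] <- pmax(w[, 1], 0)
  w[, 2] <- pmin(w[, 2], duration)
  w <- w[w[, 2] > w[, 1], , drop = FALSE]
  if (nrow(w) == 0) return(matrix(numeric(0), ncol = 2))
  w <- w[order(w[, 1]), , drop = FALSE]
  merged <- w[1, , drop = FALSE]
  for (i in seq_len(nrow(w))[-1]) {
    k <- nrow(merged)
    if (w[i, 1] <= merged[k, 2]) {
      merged[k, 2] <- max(merged[k, 2], w[i, 2])
    } else {
      merged <- rbind(merged, w[i, ])
    }
  }
  merged
}

#' Default stimulation windows for a 14-minute session
#'
#' Two high-potassium stimulation epochs: one at recording start and a
#' restimulation halfway through, each followed by a rest period.
#'
#' @param duration Session length in seconds (default 840 = 14 min).
#' @return List of (start, end) pairs in seconds.
#' @export
default_stimulation_windows <- function(duration = 840) {
  list(c(0, duration * 300 / 840), c(duration * 420 / 840,
                                     duration * 720 / 840))
}

#' Generate a ground-truth exocytotic event schedule
#'
#' Per cell, event onsets form a homogeneous Poisson process at the cell's
#' stimulated rate restricted to the stimulation windows (rate zero
#' outside). Each event draws a quantal charge from the cell's vesicle
#' population and a half-width from a log-normal; the true peak current is
#' derived through the waveform model, so the three spike characteristics
#' are mutually consistent.
#'
#' @param cells List of [cell_model()]s (may be empty).
#' @param duration Recording length (s, > 0).
#' @param stimulation_windows List of (start, end) pairs in seconds;
#'   overlapping windows are merged.
#' @param seed Optional integer seed.
#' @param model Waveform model coupling charge, half-width and peak.
#' @return Data frame with columns `cell_id`, `channel`, `onset_s`,
#'   `q_true_fC`, `t_half_true_ms`, `i_max_true_pA`, ordered by onset.
#' @export
generate_event_schedule <- function(cells, duration,
                                    stimulation_windows =
                                      default_stimulation_windows(duration),
                                    seed = NULL,
                                    model = spike_waveform_model()) {
  stopifnot(duration > 0)
  if (!is.null(seed)) set.seed(seed)
  win <- .merge_windows(stimulation_windows, duration)
  stim_time <- sum(win[, 2] - win[, 1])
  empty <- data.frame(cell_id = character(0), channel = integer(0),
                      onset_s = numeric(0), q_true_fC = numeric(0),
                      t_half_true_ms = numeric(0), i_max_true_pA = numeric(0))
  if (length(cells) == 0 || stim_time == 0) return(empty)
  pieces <- lapply(cells, function(cell) {
    n <- stats::rpois(1, cell$event_rate * stim_time)
    if (n == 0) return(NULL)
    # uniform over the union of windows, mapped through cumulative lengths
    u <- sort(stats::runif(n, 0, stim_time))
    cum <- c(0, cumsum(win[, 2] - win[, 1]))
    idx <- findInterval(u, cum, rightmost.closed = TRUE)
    onset <- win[idx, 1] + (u - cum[idx])
    q <- sample_vesicle_charges(cell$vesicles, n)
    th <- .rlnorm_meancv(n, cell$halfwidth_mean, cell$halfwidth_cv)
    data.frame(cell_id = cell$cell_id, channel = cell$channel,
               onset_s = onset, q_true_fC = q, t_half_true_ms = th,
               i_max_true_pA = waveform_peak(q, th, model))
  })
  out <- do.call(rbind, pieces)
  if (is.null(out)) return(empty)
  out <- out[order(out$onset_s), ]
  rownames(out) <- NULL
  out
}

# log-normal with given arithmetic mean and coefficient of variation
.rlnorm_meancv <- function(n, mean, cv) {
  if (cv == 0) return(rep(mean, n))
  s2 <- log(1 + cv^2)
  stats::rlnorm(n, meanlog = log(mean) - s2 / 2, sdlog = sqrt(s2))
}

#' Render noise-free current traces from an event schedule
#'
#' Superposes each event's canonical waveform on its channel. With
#' `integrate = TRUE` each sample is the window average of the analytic
#' waveform over the sampling interval (the zero-dead-time output of an
#' integrate-and-reset amplifier, computed in closed form); otherwise
#' samples are pointwise evaluations.
#'
#' @param schedule Event schedule from [generate_event_schedule()].
#' @param channels Integer vector of 0-based channels to render; every
#'   scheduled channel must be included.
#' @param duration Trace length (s).
#' @param model Waveform model.
#' @param sample_rate Sampling rate (Hz, default 10 kHz).
#' @param integrate Window-average (TRUE) or pointwise (FALSE) sampling.
#' @param metadata Metadata list stored on the result.
#' @return A [recording_array()] of noise-free traces in pA.
#' @export
render_clean_traces <- function(schedule, channels, duration,
                                model = spike_waveform_model(),
                                sample_rate = 1e4, integrate = FALSE,
                                metadata = list()) {
  stopifnot(duration > 0, sample_rate > 0)
  channels <- as.integer(channels)
  if (nrow(schedule) && !all(schedule$channel %in% channels)) {
    stop("schedule contains events on channels outside the rendered set")
  }
  n_samp <- floor(duration * sample_rate)
  traces <- matrix(0, nrow = length(channels), ncol = n_samp)
  if (nrow(schedule)) {
    dt_ms <- 1000 / sample_rate
    for (k in seq_len(nrow(schedule))) {
      ev <- schedule[k, ]
      row <- match(ev$channel, channels)
      tau_d <- ev$t_half_true_ms / model$fwhm_unit
      cut_ms <- model$s_peak * tau_d + tau_d * log(1e6)
      i0 <- floor(ev$onset_s * sample_rate)   # first sample at/after onset
      i1 <- min(n_samp - 1, ceiling((ev$onset_s + cut_ms / 1000) *
                                      sample_rate))
      if (i0 > n_samp - 1) next
      idx <- i0:i1
      t_ms <- (idx / sample_rate - ev$onset_s) * 1000
      if (integrate) {
        edges <- c(t_ms, t_ms[length(t_ms)] + dt_ms)
        cum <- .waveform_cumcharge(edges, ev$q_true_fC, ev$t_half_true_ms,
                                   model)
        vals <- diff(cum) / dt_ms
      } else {
        vals <- waveform_eval(t_ms, ev$q_true_fC, ev$t_half_true_ms, model)
      }
      traces[row, idx + 1] <- traces[row, idx + 1] + vals
    }
  }
  recording_array(traces, sample_rate, channels = channels,
                  metadata = metadata)
}

#' Write / read a ground-truth event schedule as CSV
#' @param schedule Event schedule data frame.
#' @param path CSV path.
#' @return `path` (write) or the schedule (read).
#' @export
write_schedule <- function(schedule, path) {
  data.table::fwrite(schedule, path)
  invisible(path)
}

#' @rdname write_schedule
#' @export
read_schedule <- function(path) {
  as.data.frame(data.table::fread(path))
}
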