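#' Integrate-and-reset readout model
#'
#' Each electrode has a dedicated amplifier that integrates oxidation
#' current onto a capacitor; the capacitor voltage is sampled and reset
#' once per sampling period. Column multiplexers stagger the readout of
#' the 32 rows within one period, so each row's integration window is
#' offset by a fixed sub-sample fraction.
#'
#' @param sample_rate Output sampling rate (Hz, default 10 kHz).
#' @param n_rows,n_cols Array geometry (default 32 x 32).
#' @param stagger Per-row readout offset as a fraction of the sampling
#'   period (default 1/32); `stagger * n_rows` must lie in [0, 1].
#' @param dead_time Integration dead time per period (s, default 0); must
#'   be shorter than the sampling period.
#' @return An object of class `readout_model`.
#' @export
readout_model <- function(sample_rate = 1e4, n_rows = 32L, n_cols = 32L,
                          stagger = 1 / 32, dead_time = 0) {
  stopifnot(sample_rate > 0, n_rows >= 1, n_cols >= 1)
  if (stagger < 0 || stagger * n_rows > 1) {
    stop("`stagger * n_rows` must lie in [0, 1]")
  }
  if (dead_time < 0 || dead_time >= 1 / sample_rate) {
    stop("`dead_time` must be in [0, sampling period)")
  }
  structure(list(sample_rate = sample_rate, n_rows = as.integer(n_rows),
                 n_cols = as.integer(n_cols), stagger = stagger,
                 dead_time = dead_time),
            class = "readout_model")
}

#' Device noise model
#'
#' The amplifier/electrode chain contributes band-limited noise; the
#' published figure of merit is the RMS current within the analog
#' bandwidth. Synthesis is white Gaussian at the sampling rate with the
#' per-sample SD chosen so that the in-band RMS (after an ideal low-pass
#' at `bandwidth`) equals `rms_target`. Slow perfusion-driven baseline
#' drift is modelled as a low-passed random walk of configurable RMS.
#'
#' @param rms_target In-band noise RMS (pA, default 0.9).
#' @param bandwidth Analog bandwidth (Hz, default 4400).
#' @param drift_amplitude Drift RMS (pA, default 5); set 0 to disable.
#' @param drift_corner Drift low-pass corner (Hz, default 0.5).
#' @return An object of class `noise_model`.
#' @export
noise_model <- function(rms_target = 0.9, bandwidth = 4400,
                        drift_amplitude = 5, drift_corner = 0.5) {
  if (rms_target < 0) stop("`rms_target` must be >= 0")
  stopifnot(bandwidth > 0, drift_amplitude >= 0, drift_corner > 0)
  structure(list(rms_target = rms_target, bandwidth = bandwidth,
                 drift_amplitude = drift_amplitude,
                 drift_corner = drift_corner),
            class = "noise_model")
}

#' Simulate the integrate-and-reset, multiplexed sampling of the array
#'
#' Output sample `k` of a channel in row `r` is the mean of the input
#' current over the window `[k*dt + r*stagger*dt, (k+1)*dt + r*stagger*dt
#' - dead_time]`, normalised by the full period `dt = 1/sample_rate` (so a
#' nonzero dead time loses the corresponding charge). The input must be
#' oversampled by an integer factor of at least 10.
#'
#' @param clean A [recording_array()] sampled at `>= 10 *
#'   readout$sample_rate`.
#' @param readout A [readout_model()].
#' @return A `recording_array` at the readout sampling rate.
#' @export
integrate_and_sample <- function(clean, readout = readout_model()) {
  stopifnot(inherits(clean, "recording_array"),
            inherits(readout, "readout_model"))
  m <- clean$sample_rate / readout$sample_rate
  if (abs(m - round(m)) > 1e-9 || m < 10) {
    stop("input must be oversampled by an integer factor >= 10")
  }
  m <- as.integer(round(m))
  dead_in <- as.integer(round(readout$dead_time * clean$sample_rate))
  n_in <- ncol(clean$traces)
  max_off <- as.integer(round(readout$stagger * (readout$n_rows - 1) * m))
  n_out <- (n_in - max_off) %/% m
  if (n_out < 1) stop("input too short for one output sample")
  rows <- clean$channel_map$row[match(clean$channels,
                                      clean$channel_map$channel)]
  out <- matrix(0, nrow = nrow(clean$traces), ncol = n_out)
  live <- m - dead_in
  for (i in seq_len(nrow(clean$traces))) {
    off <- as.integer(round(rows[i] * readout$stagger * m))
    x <- clean$traces[i, ]
    # cumulative sum makes every window sum an O(1) difference
    cs <- c(0, cumsum(x))
    starts <- (seq_len(n_out) - 1L) * m + off
    out[i, ] <- (cs[starts + live + 1L] - cs[starts + 1L]) / m
  }
  recording_array(out, readout$sample_rate, channel_map = clean$channel_map,
                  channels = clean$channels, metadata = clean$metadata)
}

#' Add device noise (and optional drift) to recorded traces
#'
#' White Gaussian noise with per-sample SD `rms_target *
#' sqrt((sample_rate/2) / bandwidth)` is added to every channel, so that
#' the RMS within the analog bandwidth equals `rms_target`. If
#' `noise$drift_amplitude > 0`, a low-passed random walk rescaled to that
#' RMS is added as slow baseline drift. Per-channel streams are
#' independent and reproducible given `(seed, channel order)`.
#'
#' @param x A [recording_array()].
#' @param noise A [noise_model()].
#' @param seed Optional integer seed.
#' @return A `recording_array` with noise added.
#' @export
add_noise <- function(x, noise = noise_model(), seed = NULL) {
  stopifnot(inherits(x, "recording_array"), inherits(noise, "noise_model"))
  if (noise$bandwidth > x$sample_rate / 2) {
    stop("`bandwidth` must not exceed the Nyquist frequency")
  }
  if (noise$rms_target == 0 && noise$drift_amplitude == 0) return(x)
  if (!is.null(seed)) set.seed(seed)
  n <- ncol(x$traces)
  sd_sample <- noise$rms_target * sqrt((x$sample_rate / 2) / noise$bandwidth)
  # one independent substream per channel, drawn in channel order
  ch_seeds <- sample.int(.Machine$integer.max - 1L, nrow(x$traces))
  out <- x$traces
  for (i in seq_len(nrow(out))) {
    set.seed(ch_seeds[i])
    if (noise$rms_target > 0) {
      out[i, ] <- out[i, ] + stats::rnorm(n, 0, sd_sample)
    }
    if (noise$drift_amplitude > 0) {
      out[i, ] <- out[i, ] + .drift_process(n, x$sample_rate,
                                            noise$drift_amplitude,
                                            noise$drift_corner)
    }
  }
  recording_array(out, x$sample_rate, channel_map = x$channel_map,
                  channels = x$channels, metadata = x$metadata)
}

# low-passed random walk rescaled to the requested RMS (about its mean)
.drift_process <- function(n, sample_rate, amplitude, corner) {
  rw <- cumsum(stats::rnorm(n))
  bf <- signal::butter(1, min(corner / (sample_rate / 2), 0.99),
                       type = "low")
  lp <- signal::filtfilt(bf, rw)
  lp <- lp - mean(lp)
  s <- stats::sd(lp)
  if (s == 0) return(rep(0, n))
  lp * (amplitude / s)
}

#' In-band RMS of a sampled signal via the periodogram
#'
#' Measures the RMS of the signal components at frequencies `<= f_hi`
#' (an ideal brick-wall low-pass), using Parseval's identity on the DFT.
#' Used to verify the device noise calibration.
#'
#' @param x Numeric vector.
#' @param sample_rate Sampling rate (Hz).
#' @param f_hi Upper band edge (Hz).
#' @param remove_dc Exclude the DC bin (default TRUE).
#' @return RMS in the units of `x`.
#' @export
rms_in_band <- function(x, sample_rate, f_hi, remove_dc = TRUE) {
  n <- length(x)
  X <- stats::fft(x)
  f <- (seq_len(n) - 1) / n * sample_rate
  f_alias <- pmin(f, sample_rate - f)   # fold negative frequencies
  keep <- f_alias <= f_hi
  if (remove_dc) keep[1] <- FALSE
  sqrt(sum(Mod(X[keep])^2) / n^2)
}
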