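#' Spike detection configuration
#'
#' Parameters of the event-detection chain: a 1 Hz high-pass removes
#' perfusion drift, binomial smoothing at 100 Hz suppresses wide-band
#' noise, and candidate events open where the first time-derivative of the
#' smoothed trace exceeds `threshold_multiple` times the standard
#' deviation of the background noise.
#'
#' @param highpass_hz High-pass cutoff (Hz, default 1).
#' @param smooth_hz Binomial smoothing target cutoff (-3 dB, Hz, default
#'   100).
#' @param threshold_multiple Threshold in background-noise SDs (default 5).
#' @param min_separation Minimum peak separation before the merge rule
#'   applies (ms, default 2).
#' @param baseline_window Length of the flanking segments used for local
#'   baseline estimation (ms, default 50).
#' @param derivative_window Time base of the derivative estimate (ms).
#'   The derivative is the slope between two adjacent boxcar means of
#'   this length — the discrete first derivative at the resolution the
#'   smoothing leaves. Defaults to one period of the smoothing cutoff
#'   (`1000 / smooth_hz`, i.e. 10 ms at 100 Hz); set to one sample
#'   (`1000 / sample_rate`) to recover a plain first difference.
#' @param threshold_on Which background SD the derivative is compared
#'   against: `"derivative"` (SD of the derivative statistic;
#'   dimensionally consistent, the default) or `"current"` (SD of the
#'   trace itself, preserved as the alternative reading).
#' @return An object of class `detection_config`.
#' @export
detection_config <- function(highpass_hz = 1, smooth_hz = 100,
                             threshold_multiple = 5, min_separation = 2,
                             baseline_window = 50,
                             derivative_window = 1000 / smooth_hz,
                             threshold_on = c("derivative", "current")) {
  threshold_on <- match.arg(threshold_on)
  stopifnot(highpass_hz > 0, smooth_hz > highpass_hz,
            threshold_multiple > 0, min_separation > 0,
            baseline_window > 0, derivative_window > 0)
  structure(list(highpass_hz = highpass_hz, smooth_hz = smooth_hz,
                 threshold_multiple = threshold_multiple,
                 min_separation = min_separation,
                 baseline_window = baseline_window,
                 derivative_window = derivative_window,
                 threshold_on = threshold_on),
            class = "detection_config")
}

# derivative statistic: difference of adjacent boxcar means of k samples;
# element i is the slope across trace position (i + k - 1 | i + k), so a
# rising edge at trace index j peaks near statistic index j - k + 1
.deriv_stat <- function(trace, k) {
  k <- max(1L, as.integer(k))
  n <- length(trace)
  if (n < 2 * k + 1) stop("trace too short for the derivative window")
  cs <- c(0, cumsum(trace))
  m <- (cs[(k + 1):(n + 1)] - cs[1:(n - k + 1)]) / k   # boxcar means
  m[(k + 1):length(m)] - m[1:(length(m) - k)]
}

#' Zero-phase first-order high-pass filter
#'
#' First-order Butterworth high-pass applied forward and backward
#' (`signal::filtfilt`), so the net phase is zero and the magnitude
#' response is the squared first-order response. Removes the slow
#' perfusion-driven baseline while leaving spike-band frequencies
#' untouched.
#'
#' @param trace Numeric current series (pA).
#' @param cutoff Cutoff frequency (Hz), strictly below Nyquist.
#' @param sample_rate Sampling rate (Hz).
#' @return Filtered series.
#' @export
highpass_filter <- function(trace, cutoff = 1, sample_rate = 1e4) {
  nyq <- sample_rate / 2
  if (cutoff <= 0 || cutoff >= nyq) {
    stop("`cutoff` must lie in (0, Nyquist)")
  }
  bf <- signal::butter(1, cutoff / nyq, type = "high")
  signal::filtfilt(bf, trace)
}

#' Number of binomial passes for a target cutoff
#'
#' One pass of the (1, 2, 1)/4 kernel has the exact frequency response
#' `cos^2(pi f / fs)`; `n` passes give `cos^(2n)`. Returns the smallest
#' `n` whose -3 dB frequency does not exceed `target_cutoff`.
#'
#' @param target_cutoff Target -3 dB frequency (Hz).
#' @param sample_rate Sampling rate (Hz).
#' @return Integer number of passes.
#' @export
binomial_passes <- function(target_cutoff, sample_rate) {
  if (target_cutoff <= 0 || target_cutoff >= sample_rate / 2) {
    stop("`target_cutoff` must lie in (0, Nyquist)")
  }
  # f3dB(n) = (fs/pi) * acos(2^(-1/(4n))); solve f3dB(n) <= target for n
  as.integer(ceiling(log(2) /
                       (-4 * log(cos(pi * target_cutoff / sample_rate)))))
}

#' n-fold self-convolved binomial smoothing kernel
#'
#' @param n_passes Number of (1, 2, 1)/4 passes.
#' @return Normalised kernel of length `2 * n_passes + 1` (binomial
#'   coefficients), summing to 1.
#' @export
binomial_kernel <- function(n_passes) {
  stopifnot(n_passes >= 1)
  k <- stats::dbinom(0:(2 * n_passes), 2 * n_passes, 0.5)
  k / sum(k)
}

#' Binomial low-pass smoothing
#'
#' Applies the (1, 2, 1)/4 binomial kernel repeatedly — implemented as a
#' single FFT convolution with the n-fold self-convolved kernel — with the
#' pass count chosen so the exact -3 dB point lands at or below
#' `target_cutoff`. The kernel sums to one, so DC is preserved exactly;
#' edges use constant (replicated end value) extension.
#'
#' @param trace Numeric series.
#' @param target_cutoff Target -3 dB frequency (Hz, default 100).
#' @param sample_rate Sampling rate (Hz).
#' @param n_passes Override the automatic pass count (used for kernel-level
#'   checks).
#' @return Smoothed series, same length as `trace`.
#' @export
binomial_smooth <- function(trace, target_cutoff = 100, sample_rate = 1e4,
                            n_passes = NULL) {
  if (is.null(n_passes)) {
    n_passes <- binomial_passes(target_cutoff, sample_rate)
  }
  k <- binomial_kernel(n_passes)
  m <- n_passes                       # half-width of the kernel
  padded <- c(rep(trace[1], m), trace, rep(trace[length(trace)], m))
  full <- stats::convolve(padded, rev(k), type = "open")
  # full convolution has length n + 4m; centred segment is the filtrate
  full[(2 * m + 1):(2 * m + length(trace))]
}

#' Apply the standard detection filter chain
#'
#' High-pass (perfusion drift rejection) followed by binomial smoothing.
#'
#' @param trace Numeric current series (pA).
#' @param config A [detection_config()].
#' @param sample_rate Sampling rate (Hz).
#' @return Filtered series.
#' @export
filter_trace <- function(trace, config = detection_config(),
                         sample_rate = 1e4) {
  hp <- highpass_filter(trace, config$highpass_hz, sample_rate)
  binomial_smooth(hp, config$smooth_hz, sample_rate)
}

#' Robust background-noise SD of a filtered trace and its derivative
#'
#' Uses 1.4826 x the median absolute deviation, so sparse spikes barely
#' bias the estimate; an initial whole-trace estimate drives one detection
#' pass whose events are then masked before re-estimating.
#'
#' @param trace Filtered current series (pA).
#' @param config A [detection_config()].
#' @param sample_rate Sampling rate (Hz).
#' @return List with `sd_current` (pA) and `sd_derivative` (pA / sample).
#' @export
estimate_background_sd <- function(trace, config = detection_config(),
                                   sample_rate = 1e4) {
  if (length(trace) < sample_rate) {
    stop("trace must be at least 1 s long for background estimation")
  }
  if (anyNA(trace)) stop("trace contains NA/NaN")
  k <- max(1L, as.integer(round(config$derivative_window / 1000 *
                                  sample_rate)))
  d <- .deriv_stat(trace, k)
  sd_c <- stats::mad(trace)
  sd_d <- stats::mad(d)
  if (sd_c == 0 && sd_d == 0) {
    return(list(sd_current = 0, sd_derivative = 0))
  }
  ev <- .detect_pass(trace, config, sample_rate, sd_c, sd_d)
  if (nrow(ev)) {
    mask <- rep(FALSE, length(trace))
    for (j in seq_len(nrow(ev))) mask[ev$i_start[j]:ev$i_end[j]] <- TRUE
    keep <- !mask
    if (sum(keep) > sample_rate / 2) {
      sd_c <- stats::mad(trace[keep])
      # keep derivative samples whose full 2k support is event-free
      cm <- c(0, cumsum(mask))
      di <- seq_along(d)
      clean_support <- (cm[di + 2 * k] - cm[di]) == 0
      if (sum(clean_support) > sample_rate / 2) {
        sd_d <- stats::mad(d[clean_support])
      }
    }
  }
  list(sd_current = sd_c, sd_derivative = sd_d)
}

#' Detect quantal spikes on one filtered trace
#'
#' Candidate events open where the first difference of the trace exceeds
#' `threshold_multiple` times the background-noise SD (estimated robustly
#' with one event-masked re-estimation pass). For each candidate the peak
#' is the trace maximum after the crossing; the event start is the last
#' pre-peak sample at or below the local baseline (median of the
#' `baseline_window` preceding the crossing), and the end is the first
#' post-peak return to within one current-SD of baseline (or the local
#' minimum before the next event). Peaks closer than `min_separation`
#' whose intervening trough stays above 50% of both peak heights are
#' merged.
#'
#' @param trace Filtered current series (pA); must be NA-free.
#' @param config A [detection_config()].
#' @param sample_rate Sampling rate (Hz).
#' @param channel Channel index stored on the result (default 0).
#' @return Data frame of events: `channel`, `t_start_s`, `t_peak_s`,
#'   `t_end_s`, sample indices `i_start`/`i_peak`/`i_end` (1-based) and
#'   `baseline_pA`, ordered and non-overlapping.
#' @export
detect_spikes <- function(trace, config = detection_config(),
                          sample_rate = 1e4, channel = 0L) {
  if (anyNA(trace)) stop("trace contains NA/NaN; filter and clean it first")
  sds <- estimate_background_sd(trace, config, sample_rate)
  ev <- .detect_pass(trace, config, sample_rate, sds$sd_current,
                     sds$sd_derivative)
  if (nrow(ev)) {
    ev$channel <- as.integer(channel)
    ev$t_start_s <- (ev$i_start - 1) / sample_rate
    ev$t_peak_s <- (ev$i_peak - 1) / sample_rate
    ev$t_end_s <- (ev$i_end - 1) / sample_rate
    ev <- ev[, c("channel", "t_start_s", "t_peak_s", "t_end_s",
                 "i_start", "i_peak", "i_end", "baseline_pA")]
  } else {
    ev <- data.frame(channel = integer(0), t_start_s = numeric(0),
                     t_peak_s = numeric(0), t_end_s = numeric(0),
                     i_start = integer(0), i_peak = integer(0),
                     i_end = integer(0), baseline_pA = numeric(0))
  }
  ev
}

# single detection pass at fixed noise SDs; deterministic
.detect_pass <- function(trace, config, sample_rate, sd_c, sd_d) {
  n <- length(trace)
  kd <- max(1L, as.integer(round(config$derivative_window / 1000 *
                                   sample_rate)))
  d <- .deriv_stat(trace, kd)
  thr <- config$threshold_multiple *
    if (config$threshold_on == "derivative") sd_d else sd_c
  above <- d > thr
  empty <- data.frame(i_start = integer(0), i_peak = integer(0),
                      i_end = integer(0), baseline_pA = numeric(0))
  if (!any(above)) return(empty)
  # statistic index i straddles trace position i + kd - 1; the event rise
  # lies inside the leading boxcar, so the crossing maps there
  starts <- which(above & !c(FALSE, above[-length(above)])) + kd - 1L
  starts <- pmin(starts, n - 1L)
  bw <- max(1L, as.integer(round(config$baseline_window / 1000 *
                                   sample_rate)))
  sep <- max(1L, as.integer(round(config$min_separation / 1000 *
                                    sample_rate)))
  look <- as.integer(round(0.1 * sample_rate))  # peak search, 100 ms
  far <- as.integer(round(0.5 * sample_rate))   # boundary search, 500 ms
  events <- list()
  last_end <- 0L
  for (i in starts) {
    if (i <= last_end) next              # inside the previous event
    hi <- min(n, i + look)
    i_peak <- i - 1L + which.max(trace[i:hi])
    while (i_peak == hi && hi < min(n, i + far)) {   # peak beyond horizon
      hi <- min(n, hi + look)
      i_peak <- i - 1L + which.max(trace[i:hi])
    }
    b_lo <- max(1L, i - bw)
    baseline <- stats::median(trace[b_lo:max(b_lo, i - 1L)])
    # start: last pre-peak sample at/below baseline
    s_lo <- max(1L, i_peak - far)
    pre <- trace[s_lo:i_peak]
    under <- which(pre <= baseline)
    i_start <- if (length(under)) s_lo - 1L + under[length(under)] else s_lo
    i_start <- min(i_start, i_peak - 1L)
    i_start <- max(i_start, 1L)
    # end: first post-peak return to baseline + 1 current-SD
    e_hi <- min(n, i_peak + far)
    post <- trace[i_peak:e_hi]
    back <- which(post <= baseline + sd_c)
    i_end <- if (length(back)) i_peak - 1L + back[1]
             else i_peak - 1L + which.min(post)
    i_end <- max(i_end, i_peak + 1L)
    i_end <- min(i_end, n)
    if (i_end <= i_peak || i_start >= i_peak) next
    # filter edge transients: an event this close to either end has no
    # usable baseline and cannot be measured
    if (i_peak <= bw || i_peak > n - bw) next
    events[[length(events) + 1]] <-
      list(i_start = as.integer(i_start), i_peak = as.integer(i_peak),
           i_end = as.integer(i_end), baseline = baseline)
    last_end <- i_end
  }
  if (!length(events)) return(empty)
  ev <- data.frame(
    i_start = vapply(events, `[[`, integer(1), "i_start"),
    i_peak = vapply(events, `[[`, integer(1), "i_peak"),
    i_end = vapply(events, `[[`, integer(1), "i_end"),
    baseline_pA = vapply(events, `[[`, numeric(1), "baseline")
  )
  ev <- ev[!duplicated(ev$i_peak), , drop = FALSE]
  ev <- ev[order(ev$i_peak), , drop = FALSE]
  # merge unresolved twin peaks: within min_separation a trough above 50%
  # of both peaks merges; up to the derivative window (the detector's
  # temporal resolution) a trough above 50% of the smaller peak does
  merged <- ev[1, , drop = FALSE]
  if (nrow(ev) > 1) {
    for (k in 2:nrow(ev)) {
      j <- nrow(merged)
      a <- merged[j, ]; b <- ev[k, ]
      trough <- min(trace[a$i_peak:b$i_peak]) - a$baseline_pA
      pk_a <- trace[a$i_peak] - a$baseline_pA
      pk_b <- trace[b$i_peak] - b$baseline_pA
      gap <- b$i_peak - a$i_peak
      do_merge <-
        (gap < sep && trough > 0.5 * pk_a && trough > 0.5 * pk_b) ||
        (gap < max(sep, kd) && trough > 0.5 * min(pk_a, pk_b))
      if (do_merge) {
        merged$i_end[j] <- max(a$i_end, b$i_end)
        merged$i_start[j] <- min(a$i_start, b$i_start)
        if (pk_b > pk_a) merged$i_peak[j] <- b$i_peak
      } else {
        merged <- rbind(merged, b)
      }
    }
  }
  # enforce non-overlap: split at the trough between adjacent peaks
  if (nrow(merged) > 1) {
    for (k in 2:nrow(merged)) {
      if (merged$i_start[k] <= merged$i_end[k - 1]) {
        lo <- merged$i_peak[k - 1]; hi <- merged$i_peak[k]
        cut <- lo - 1L + which.min(trace[lo:hi])
        merged$i_end[k - 1] <- max(cut - 1L, merged$i_peak[k - 1] + 1L)
        merged$i_start[k] <- min(cut, merged$i_peak[k] - 1L)
      }
    }
  }
  rownames(merged) <- NULL
  merged
}

#' Detect spikes on every channel of a recording
#'
#' Filters each channel with the standard chain and runs
#' [detect_spikes()], returning one combined event table.
#'
#' @param rec A [recording_array()] of raw traces.
#' @param config A [detection_config()].
#' @return Data frame of events across channels (columns as in
#'   [detect_spikes()]), plus the filtered traces as attribute
#'   `"filtered"` when `keep_filtered = TRUE`.
#' @param keep_filtered Attach the filtered trace matrix (needed when
#'   metrics are computed next; default TRUE).
#' @export
detect_recording <- function(rec, config = detection_config(),
                             keep_filtered = TRUE) {
  stopifnot(inherits(rec, "recording_array"))
  filt <- if (keep_filtered) matrix(0, nrow(rec$traces), ncol(rec$traces))
          else NULL
  out <- vector("list", nrow(rec$traces))
  for (i in seq_len(nrow(rec$traces))) {
    f <- filter_trace(rec$traces[i, ], config, rec$sample_rate)
    if (keep_filtered) filt[i, ] <- f
    out[[i]] <- detect_spikes(f, config, rec$sample_rate,
                              channel = rec$channels[i])
  }
  ev <- do.call(rbind, out)
  rownames(ev) <- NULL
  if (keep_filtered) attr(ev, "filtered") <- filt
  ev
}
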