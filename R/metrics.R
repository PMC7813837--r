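#' Convert spike charge to a molecule count
#'
#' Each analyte molecule transfers `electrons_per_molecule` electrons on
#' oxidation (two for dopamine), so a spike of integrated charge `Q`
#' reflects `N = Q / (2 q_e)` released molecules.
#'
#' @param q_fC Charge in fC (>= 0); may be a vector.
#' @param constants See [physical_constants()].
#' @param round_count Round to the nearest whole molecule (default TRUE).
#' @return Molecule count(s).
#' @export
molecules_from_charge <- function(q_fC, constants = physical_constants(),
                                  round_count = TRUE) {
  if (any(q_fC < 0)) stop("charge must be non-negative")
  n <- q_fC * 1e-15 /
    (constants$electrons_per_molecule * constants$elementary_charge)
  if (round_count) round(n) else n
}

# cube root of quantal size expressed in attomole^(1/3)
.q_cuberoot_amol <- function(n_molecules, constants = physical_constants()) {
  (n_molecules / constants$avogadro / 1e-18)^(1 / 3)
}

#' Noise RMS integrated over an event duration
#'
#' Averaging a white, band-limited noise current over an event of length
#' `T` leaves an effective bandwidth `f_eff = 1 / (2 T)`, reducing the RMS
#' by `sqrt(f_eff / bandwidth)`. If the event is so short that `f_eff`
#' exceeds the noise bandwidth there is no reduction.
#'
#' @param rms Wide-band noise RMS (pA).
#' @param bandwidth Noise bandwidth (Hz).
#' @param duration_ms Event duration (ms).
#' @return Effective RMS over the event (pA).
#' @export
integrated_noise <- function(rms, bandwidth, duration_ms) {
  stopifnot(rms > 0, bandwidth > 0, duration_ms > 0)
  f_eff <- 1 / (2 * duration_ms / 1000)
  if (f_eff > bandwidth) return(rms)
  rms * sqrt(f_eff / bandwidth)
}

#' Quantal-size-equivalent detection floor in molecules
#'
#' The smallest quantal event distinguishable from noise: the integrated
#' noise RMS over the event duration, times the duration, converted from
#' charge to molecules.
#'
#' @inheritParams integrated_noise
#' @param constants See [physical_constants()].
#' @return Molecule count (noise-equivalent quantal size).
#' @export
detection_limit_molecules <- function(rms, bandwidth, duration_ms,
                                      constants = physical_constants()) {
  if (duration_ms == 0) return(0)
  q_fC <- integrated_noise(rms, bandwidth, duration_ms) * duration_ms
  molecules_from_charge(q_fC, constants)
}

#' Measure the quantal characteristics of one detected spike
#'
#' The local baseline is the linear interpolation between the means of
#' `baseline_window`-long segments flanking the event. Reported metrics:
#' `i_max` (baseline-to-peak amplitude), `q` (trapezoidal integral of the
#' baseline-subtracted current over the event), `t_half` (width at half
#' amplitude with sub-sample linear interpolation at both crossings), the
#' molecule count `q / (2 q_e)`, and the cube root of quantal size in
#' attomole^(1/3). Events clipped by the trace edge are flagged
#' `unreliable` and excluded from downstream statistics.
#'
#' @param trace Filtered current series (pA).
#' @param event One-row event (list or data frame row) with `i_start`,
#'   `i_peak`, `i_end` sample indices as produced by [detect_spikes()].
#' @param sample_rate Sampling rate (Hz).
#' @param baseline_window Flanking-segment length (ms, default 50).
#' @param constants See [physical_constants()].
#' @return One-row data frame: `i_max_pA`, `t_half_ms`, `q_fC`,
#'   `n_molecules`, `q_amol_cuberoot`, `unreliable`.
#' @export
measure_spike <- function(trace, event, sample_rate = 1e4,
                          baseline_window = 50,
                          constants = physical_constants()) {
  n <- length(trace)
  i_start <- event$i_start; i_peak <- event$i_peak; i_end <- event$i_end
  stopifnot(i_start >= 1, i_end <= n, i_start < i_peak, i_peak < i_end)
  bw <- max(1L, round(baseline_window / 1000 * sample_rate))
  unreliable <- (i_start - bw < 1) || (i_end + bw > n)
  pre_lo <- max(1L, i_start - bw)
  post_hi <- min(n, i_end + bw)
  pre_mean <- mean(trace[pre_lo:max(pre_lo, i_start - 1L)])
  post_mean <- mean(trace[min(post_hi, i_end + 1L):post_hi])
  idx <- i_start:i_end
  # baseline interpolated between the flanking segment centres
  x0 <- (pre_lo + max(pre_lo, i_start - 1L)) / 2
  x1 <- (min(post_hi, i_end + 1L) + post_hi) / 2
  base <- pre_mean + (post_mean - pre_mean) * (idx - x0) / (x1 - x0)
  y <- trace[idx] - base
  peak_rel <- i_peak - i_start + 1L
  i_max <- y[peak_rel]
  dt_ms <- 1000 / sample_rate
  q_fC <- sum((y[-1] + y[-length(y)]) / 2) * dt_ms   # trapezoid; pA*ms = fC
  half <- i_max / 2
  t_half <- .halfwidth_interp(y, peak_rel, half) * dt_ms
  n_mol <- molecules_from_charge(max(q_fC, 0), constants)
  data.frame(
    i_max_pA = i_max, t_half_ms = t_half, q_fC = q_fC,
    n_molecules = n_mol,
    q_amol_cuberoot = .q_cuberoot_amol(n_mol, constants),
    unreliable = unreliable
  )
}

# width (in samples) at level `half`, linear interpolation at both flanks
.halfwidth_interp <- function(y, peak, half) {
  # rising crossing: last sample before the peak at/below half
  lo <- which(y[seq_len(peak)] <= half)
  if (length(lo)) {
    j <- lo[length(lo)]
    frac <- if (y[j + 1] == y[j]) 0 else (half - y[j]) / (y[j + 1] - y[j])
    left <- j + frac
  } else left <- 1
  # falling crossing: first sample after the peak at/below half
  post <- y[peak:length(y)]
  hi <- which(post <= half)
  if (length(hi)) {
    j <- peak + hi[1] - 1L
    frac <- if (y[j] == y[j - 1]) 0 else (y[j - 1] - half) / (y[j - 1] - y[j])
    right <- (j - 1L) + frac
  } else right <- length(y)
  right - left
}

#' Measure all detected events of a recording
#'
#' Applies [measure_spike()] to every event, using the filtered traces
#' attached by [detect_recording()].
#'
#' @param events Event table from [detect_recording()] (with the
#'   `"filtered"` attribute) — or supply `filtered` explicitly.
#' @param rec The [recording_array()] the events came from.
#' @param filtered Optional matrix of filtered traces (channels x samples).
#' @param baseline_window Flanking-segment length (ms).
#' @param constants See [physical_constants()].
#' @param drop_unreliable Drop edge-clipped events (default TRUE).
#' @return Event metric table: detection columns plus `i_max_pA`,
#'   `t_half_ms`, `q_fC`, `n_molecules`, `q_amol_cuberoot`.
#' @export
measure_events <- function(events, rec, filtered = NULL,
                           baseline_window = 50,
                           constants = physical_constants(),
                           drop_unreliable = TRUE) {
  if (is.null(filtered)) filtered <- attr(events, "filtered")
  if (is.null(filtered)) stop("no filtered traces supplied")
  if (nrow(events) == 0) {
    return(cbind(events, data.frame(i_max_pA = numeric(0),
                                    t_half_ms = numeric(0),
                                    q_fC = numeric(0),
                                    n_molecules = numeric(0),
                                    q_amol_cuberoot = numeric(0),
                                    unreliable = logical(0))))
  }
  rows <- match(events$channel, rec$channels)
  mets <- lapply(seq_len(nrow(events)), function(k) {
    measure_spike(filtered[rows[k], ], events[k, ], rec$sample_rate,
                  baseline_window, constants)
  })
  out <- cbind(as.data.frame(events), do.call(rbind, mets))
  if (drop_unreliable) out <- out[!out$unreliable, , drop = FALSE]
  rownames(out) <- NULL
  out
}
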