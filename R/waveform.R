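#' Canonical amperometric spike waveform
#'
#' Parametric shape used to turn a scheduled (charge, half-width) pair into a
#' current trace: `I(t) = A * (1 - exp(-t / tau_r)) * exp(-t / tau_d)` for
#' `t >= 0`, a fast exponential rise followed by an exponential decay. The
#' rise constant is tied to the decay constant by a fixed ratio
#' (`tau_r = rise_to_decay_ratio * tau_d`), the decay constant is solved so
#' the full width at half maximum equals the requested half-width, and the
#' amplitude `A` is scaled so the time integral equals the requested charge.
#' The peak current is therefore emergent: linear in charge and
#' inverse-linear in half-width.
#'
#' @param rise_to_decay_ratio Ratio `tau_r / tau_d`, strictly in (0, 1).
#' @return An object of class `spike_waveform_model` carrying the ratio and
#'   precomputed unit-shape constants (peak location/height and FWHM of the
#'   shape with `tau_d = 1`).
#' @export
spike_waveform_model <- function(rise_to_decay_ratio = 0.25) {
  if (!is.numeric(rise_to_decay_ratio) || length(rise_to_decay_ratio) != 1 ||
      rise_to_decay_ratio <= 0 || rise_to_decay_ratio >= 1) {
    stop("`rise_to_decay_ratio` must be a single number in (0, 1)")
  }
  r <- rise_to_decay_ratio
  g <- function(s) (1 - exp(-s / r)) * exp(-s)   # unit shape, tau_d = 1
  s_peak <- r * log(1 + 1 / r)
  g_max <- g(s_peak)
  half <- g_max / 2
  s_lo <- stats::uniroot(function(s) g(s) - half, c(1e-12, s_peak),
                         tol = 1e-12)$root
  # decay side: g(s) <= exp(-s), so the crossing is below -log(half) + margin
  s_hi <- stats::uniroot(function(s) g(s) - half,
                         c(s_peak, -log(half) + 1), tol = 1e-12)$root
  structure(
    list(rise_to_decay_ratio = r, s_peak = s_peak, g_max = g_max,
         fwhm_unit = s_hi - s_lo),
    class = "spike_waveform_model"
  )
}

# tau_d (ms) and amplitude A (pA) realising charge q_fC and half-width
# t_half_ms; note 1 fC / 1 ms = 1 pA, so mixed ms/fC units stay consistent.
.waveform_params <- function(q_fC, t_half_ms, model) {
  tau_d <- t_half_ms / model$fwhm_unit
  r <- model$rise_to_decay_ratio
  # integral of unit shape over [0, Inf) is tau_d / (1 + r) in time units
  A <- q_fC * (1 + r) / tau_d
  list(tau_d = tau_d, tau_r = r * tau_d, A = A)
}

#' Peak current of the canonical spike waveform
#'
#' @param q_fC Quantal charge (fC); may be a vector.
#' @param t_half_ms Half-width, FWHM (ms); recycled against `q_fC`.
#' @param model A [spike_waveform_model()].
#' @return Peak current in pA.
#' @export
waveform_peak <- function(q_fC, t_half_ms, model = spike_waveform_model()) {
  if (any(!is.finite(q_fC)) || any(q_fC <= 0)) {
    stop("`q_fC` must be positive and finite")
  }
  if (any(!is.finite(t_half_ms)) || any(t_half_ms <= 0)) {
    stop("`t_half_ms` must be positive and finite")
  }
  p <- .waveform_params(q_fC, t_half_ms, model)
  p$A * model$g_max
}

#' Evaluate the spike waveform at given times
#'
#' @inheritParams waveform_peak
#' @param t_ms Times since event onset (ms); values before onset give 0.
#' @return Current in pA at each time.
#' @export
waveform_eval <- function(t_ms, q_fC, t_half_ms,
                          model = spike_waveform_model()) {
  p <- .waveform_params(q_fC, t_half_ms, model)
  out <- numeric(length(t_ms))
  pos <- t_ms > 0
  tp <- t_ms[pos]
  out[pos] <- p$A * (1 - exp(-tp / p$tau_r)) * exp(-tp / p$tau_d)
  out
}

# Closed-form integral of the waveform over [0, t_ms], in fC.
.waveform_cumcharge <- function(t_ms, q_fC, t_half_ms, model) {
  p <- .waveform_params(q_fC, t_half_ms, model)
  kappa <- 1 / p$tau_r + 1 / p$tau_d
  t <- pmax(t_ms, 0)
  p$A * (p$tau_d * (1 - exp(-t / p$tau_d)) - (1 - exp(-kappa * t)) / kappa)
}
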