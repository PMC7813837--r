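# Shared fixtures, built in code at test time.

# one-event schedule row in the canonical column layout
spike_row <- function(onset_s, q_fC, t_half_ms, channel = 0L,
                      model = spike_waveform_model()) {
  data.frame(cell_id = "cell", channel = as.integer(channel),
             onset_s = onset_s, q_true_fC = q_fC,
             t_half_true_ms = t_half_ms,
             i_max_true_pA = waveform_peak(q_fC, t_half_ms, model))
}

# analytic peak time of a scheduled event (s)
true_peak_time <- function(schedule, model = spike_waveform_model()) {
  tau_d <- schedule$t_half_true_ms / model$fwhm_unit
  schedule$onset_s + model$s_peak * tau_d / 1000
}

# ground-truth schedule recast with measured-metric column names, so it can
# feed summarize_cells()/group_report() directly
schedule_as_events <- function(schedule) {
  out <- schedule
  out$i_max_pA <- out$i_max_true_pA
  out$t_half_ms <- out$t_half_true_ms
  out$q_fC <- out$q_true_fC
  out$n_molecules <- molecules_from_charge(out$q_fC)
  out$q_amol_cuberoot <-
    (out$n_molecules / physical_constants()$avogadro / 1e-18)^(1 / 3)
  out
}

# white noise calibrated like the device model, without drift
device_noise_trace <- function(n, seed, sample_rate = 1e4) {
  rec <- recording_array(matrix(0, 1, n), sample_rate)
  rec <- add_noise(rec, noise_model(drift_amplitude = 0), seed = seed)
  rec$traces[1, ]
}
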