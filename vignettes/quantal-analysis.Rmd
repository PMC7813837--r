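---
title: "Quantal analysis of amperometric array recordings: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantal analysis of amperometric array recordings: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(ampquant)
```

## The problem

Catecholamine-secreting cells such as PC-12 release neurotransmitter one
vesicle at a time. When a cell sits on a polarised microelectrode, each
fusion event oxidises the released dopamine (two electrons per molecule)
and produces a brief current spike of a few picoamperes. Three numbers
summarise each spike: the baseline-to-peak amplitude $I_{max}$, the
half-width $t_{1/2}$ (duration at half amplitude), and the quantal size
$Q$ — the time integral of the current, proportional to the number of
molecules released:

$$N = \frac{Q}{2\,q_e}.$$

A 32×32 CMOS electrode array records up to 1024 such channels at 10 kHz
simultaneously, with an in-band noise floor near 0.9 pA RMS over a 4.4 kHz
bandwidth. `ampquant` implements the full computation around such
recordings: a generative model of the experiment, the device measurement
chain, the spike-detection chain, per-spike quantal metrics, and the
cell-level group statistics used to quantify pharmacological modulation
(e.g. L-Dopa raising vesicular loading). Because the underlying raw
recordings are not publicly archived, the synthetic generator is a
first-class component: it defines the study conditions under which every
claim in this package is tested.

## Generative model

**Vesicle population.** Vesicle diameters $\phi$ are Gaussian; quantal
charge follows the cube law $Q = c\,\phi^3$. Working in diameter units of
attomole$^{1/3}$ makes $c$ the oxidation charge of one attomole
(≈193 fC), so $Q^{1/3}$ expressed in attomole$^{1/3}$ is Gaussian — the
scale on which quantal-size histograms are Gaussian and on which the
control group is calibrated (mean ≈ 0.40, SD 0.08 attomole$^{1/3}$,
equivalent to a mean quantal charge of 14.3 fC). Diameters are truncated
to positive values by rejection sampling; at the CVs used here (≤ 0.25)
the truncation is negligible, which is why a plain truncated-normal
quadrature oracle reproduces the sampled moments.

**Event trains.** Each cell occupies one electrode and fires as a
homogeneous Poisson process during stimulation windows (two
high-potassium epochs per session, the second a restimulation halfway
through; rate zero outside). Per-cell rates are set so a 16-cell control
cohort yields ≈477 events and a 63-cell treated cohort ≈3534 events over
the stimulated epochs of a 14-min session.

**Spike waveform.** The source experiment does not publish a waveform, so
the package defines one:
$$I(t) = A\,(1 - e^{-t/\tau_r})\,e^{-t/\tau_d}, \qquad \tau_r = 0.25\,\tau_d,$$
a fast rise and exponential decay matching the qualitative shape of
recorded quantal spikes. $\tau_d$ is solved so the FWHM equals the drawn
half-width, and $A$ is scaled so the integral equals the drawn charge.
$I_{max}$ is therefore *emergent* (linear in $Q$, inverse-linear in
$t_{1/2}$): with the control means $Q = 14.3$ fC and $t_{1/2} = 7.33$ ms
it comes out at 1.60 pA, the same order as the measured 1.30 pA mean.
Half-widths are log-normal with CV 0.4 (positivity and right skew typical
of amperometric data); $Q$ and $t_{1/2}$ are drawn independently because
the experiment treats the three characteristics as measured outputs, not
as a joint law.

## Device readout

Each amplifier integrates current onto a capacitor and is sampled and
reset once per 100 µs period; column multiplexers stagger the 32 rows by
1/32 of the period. `integrate_and_sample()` implements the window
average (optionally with dead time); for pipeline-scale simulation the
same window average is computed in closed form from the waveform's
antiderivative, so rendered traces are charge-exact without oversampling.
Sub-sample stagger only matters for events shorter than 0.1 ms and is
retained for architectural fidelity.

Noise is synthesised white and Gaussian at the sampling rate with
per-sample SD $0.9\sqrt{(f_s/2)/4400}$ pA, so the RMS inside the 4.4 kHz
analog bandwidth equals the 0.9 pA target; the device's true spectral
shape is not published, so white-in-band is assumed. Perfusion drift is
modelled as a low-passed random walk (default 5 pA RMS below a 0.5 Hz
corner) — large enough that the 1 Hz high-pass in detection is genuinely
exercised.

## Detection chain

1. **1 Hz first-order Butterworth high-pass**, applied forward and
   backward (`signal::filtfilt`), removing drift with zero phase shift.
   Amplitude, not phase, matters for the metrics, so the squared
   first-order magnitude response is the analytic reference.
2. **Binomial smoothing at 100 Hz**: repeated (1,2,1)/4 passes, with the
   pass count chosen from the *exact* response $\cos^{2n}(\pi f/f_s)$ as
   the smallest $n$ whose −3 dB point is at or below 100 Hz (352 passes
   at 10 kHz), applied as a single FFT convolution with the equivalent
   binomial kernel. The kernel sums to one, so DC gain is exactly 1.
3. **5σ derivative threshold.** Candidate events open where the first
   time-derivative of the smoothed trace exceeds five robust standard
   deviations (1.4826×MAD) of the background derivative, with one
   detect–mask–re-estimate pass.

The derivative's time base is the one genuinely open design choice. A
one-sample difference at 10 kHz of a 100 Hz-smoothed trace compares a
~0.1 ms increment against noise of the same spectral content, and its
signal-to-noise ratio is capped near 6 for a canonical 1.30 pA / 7.33 ms
spike — a 5σ cut then misses nearly half of such spikes. `ampquant`
instead estimates the derivative as the slope between two adjacent boxcar
means spanning one period of the smoothing cutoff (10 ms at 100 Hz,
`derivative_window`): the discrete first derivative at the resolution the
smoothing actually leaves. This restores single-spike detection of the
canonical spike to ≈98% (the Monte-Carlo in the test suite) while keeping
the published 5σ criterion intact. Setting `derivative_window` to one
sample recovers the literal per-sample difference; `threshold_on =
"current"` preserves the alternative reading of "SD of the background
noise" against the raw current SD.

**Boundary conventions** (the source defers these to its analysis
software, so they are declared here): the local baseline is the median of
the 50 ms preceding the threshold crossing; the event starts at the last
pre-peak sample at or below baseline; it ends at the first post-peak
return to within one current-SD of baseline (or the pre-next-event
minimum); peaks closer than 2 ms whose trough stays above 50% of both
peaks are merged, and within the derivative window a trough above 50% of
the smaller peak also merges (the detector cannot resolve events inside
its own time base). Events peaking within one baseline window of a trace
edge are discarded — they cannot be baselined and coincide with filter
edge transients.

## Metrics

Per event, the baseline is interpolated linearly between the means of
50-ms flanking segments; $I_{max}$ is peak minus baseline, $Q$ the
trapezoidal integral of the baseline-subtracted current, and $t_{1/2}$
the width at half amplitude with sub-sample linear interpolation at both
crossings (discretisation error < 1.5% at 10 kHz for ~7 ms spikes).
Molecule counts use fixed CODATA constants with the two-electron
stoichiometry (configurable for other analytes). Edge-clipped events are
flagged unreliable and excluded from statistics.

The 100 Hz smoothing itself biases the measured characteristics of
~7 ms spikes: the peak is attenuated by ≈11% and the half-width broadened
by ≈13% (the two nearly cancel in $Q$, which is only truncated by the
end-of-event rule, ≈ −6%). These are properties of the prescribed
measurement chain, not defects; the reference experiment's printed values
went through the same chain.

## Detection-limit arithmetic

Averaging band-limited white noise over an event of duration $T$ leaves
an effective bandwidth $1/(2T)$, so the integrated noise for 5-ms events
is $0.9\sqrt{100/4400} \approx 0.136$ pA RMS, and the noise-equivalent
quantal size is `detection_limit_molecules(0.9, 4400, 5)` ≈ 2100
molecules. The same identity is cross-checked against a boxcar-averaging
Monte-Carlo in the test suite.

## Group statistics

The statistical unit is the **cell**: the median of each characteristic
over a cell's spikes is that cell's single value, preventing highly
active cells from dominating. Groups are compared with a two-tailed
pooled-variance Student's t test (Welch available; the two coincide for
equal sizes and variances, and the heavily unbalanced 16-vs-63 design is
why the option is exposed). Percent change is
$100\,(\bar{x}_T - \bar{x}_C)/\bar{x}_C$, reported to the nearest integer.
Per-spike $Q^{1/3}$ is fitted by maximum likelihood with a descriptive
Kolmogorov–Smirnov normality p-value (parameters estimated from the same
data, so the p-value is indicative). Box statistics use type-7 quantiles
with whiskers drawn to the extremes, and no multiple-testing correction
is applied across the four characteristics — matching the reporting
conventions being emulated. Histogram binning is uniform over the pooled
range with a configurable bin count.

## What passing tests do and do not show

The generator emulates sparse quantal spikes on calibrated band-limited
noise with drift, one cell per electrode. It does **not** model cell
clumps sharing an electrode, pre-spike feet, kiss-and-run partial
release, overlapping-spike deconvolution beyond the trough rule, or
electrode-to-cell diffusion loss. Green tests therefore validate the
computation chain under the declared generative conditions, not the
biology of any particular recording.

Two quantitative caveats are intrinsic to those conditions and are
computed by the acceptance script itself:

* **Recall ceiling.** The generative population's weak tail (low $Q$,
  long $t_{1/2}$) contains events whose *matched-filter* SNR is below 5;
  the acceptance script reports this ceiling
  (`matched_filter_recall_ceiling_pct`, ≈88% for the control
  population). No 5σ detector can recall more; the implemented chain
  reaches ≈75% on control-like and ≈88% on treated-like cohorts (larger
  spikes), as the acceptance script reports.
* **Selection bias.** Because detection preferentially drops weak
  events, recovered per-cell medians of $Q$ and $I_{max}$ sit well above
  the generative medians (tens of percent at the control settings). The
  recovered two-group *contrast* remains strongly significant because
  both cohorts are subject to the same selection.

## Problem sizes and numerical choices

Simulated sessions in the analysis scripts, the acceptance script and
the tests use 4-minute sessions with 8 control and 16 treated cells
(preserving the per-cell event rates and the group unbalance of the
14-minute reference design), four event-free channels for false-positive
counting, and 20 full-scale replicate schedules for the power check —
sizes chosen so the whole analysis reruns in minutes on one CPU while
keeping every per-cell spike count near the reference regime. Seeds
propagate from a single master seed through `derive_seed()`; identical
configuration and seed give byte-identical artifacts. Waveform tails are
rendered to $10^{-6}$ of the envelope so trapezoidal charge is conserved
to better than $10^{-3}$ relative. HDF5 is not used in this build; the
on-disk container is long-format CSV with a YAML sidecar holding the
sampling metadata and channel map.
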