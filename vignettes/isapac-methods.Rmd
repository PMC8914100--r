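---
title: "Infraslow phase-amplitude coupling: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Infraslow phase-amplitude coupling: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(isapac)
```

## The problem

Infraslow activity (ISA) is cortical electrical activity in the 0.01-0.1 Hz
band. Its phase has been linked to slow fluctuations of autonomic arousal:
the amplitude of the galvanic skin response (GSR, a skin-conductance
measure of sympathetic tone) varies systematically with the momentary ISA
phase, with a preferred phase that differs between individuals. `isapac`
implements the statistical machinery for this kind of analysis: phase
extraction at infraslow frequencies, binned phase-amplitude coupling
quantified by a d-prime contrast, phase-coherence statistics over channels
and trials with permutation nulls, lag scans against peripheral signals,
and group comparisons. A synthetic session generator with full ground
truth makes every stage testable without access to recordings.

## Signal model and preprocessing

For each EEG channel $x(t)$ sampled at rate $f_s$ (256 Hz for BioSemi
recordings), the ISA component is isolated with a zero-phase Butterworth
bandpass at 0.01-0.1 Hz (order 2 per pass, applied forward and backward,
so the effective order is 4 and the phase response exactly zero). The
analytic signal $x(t) + i\,\mathcal{H}[x](t)$ then yields the
instantaneous phase $\theta(t) \in (-\pi, \pi]$ and envelope $a(t) \ge 0$.
Instantaneous frequency is $\dot{\theta}/2\pi$ from the unwrapped phase
with central finite differences. Peripheral channels (GSR, respiration)
are highpass-filtered at 0.01 Hz to remove drifts. Everything is computed
at the native rate and only then decimated to the 1 Hz analysis rate; a
regression test pins this order, because Hilbert-transforming an already
decimated series gives measurably different phases near the band edge.

Choices the data do not dictate, declared once:

* **Filter family/order.** A Butterworth was chosen for its flat passband;
  at normalized cutoffs as extreme as $10^{-4}$ higher orders become
  numerically fragile while order 2 per pass is stable and attenuates a
  1 Hz artifact band by ~80 dB after the two passes. Both are
  configurable (`order`, band edges).
* **Edge guard.** The Hilbert transform is global and the filter's
  transient at 0.01 Hz lasts on the order of a minute, so the first and
  last 100 s (configurable) of every series are flagged unreliable and
  excluded from statistics by default.
* **Decimation.** Plain subsampling, with no extra anti-alias filter: the
  series is already confined below 0.1 Hz, far under the 0.5 Hz output
  Nyquist frequency.
* **Non-finite samples** are a construction-time error, never silently
  interpolated, so every downstream count refers to real data.

## Phase-amplitude coupling

The phase circle is divided into eight equal bins of width $\pi/4$
covering $(-\pi, \pi]$. For one EEG channel and one peripheral channel,
every 1 Hz sample contributes its GSR "amplitude" to the bin of the
simultaneous EEG phase. The bins with maximal and minimal median
amplitude are identified, and their amplitude distributions contrasted
with the discriminability index

$$d' = \frac{|\mu_1 - \mu_2|}{(\sigma_1 + \sigma_2)/2},$$

where $(\mu_k, \sigma_k)$ are mean and standard deviation of the two
bins' samples, plus a two-sample t-test. Conventions:

* **Median selects, mean contrasts.** Extreme bins are chosen by their
  median (robust to skewed electrodermal amplitudes); $d'$ and the t-test
  then use the moments of the chosen bins. Selection by mean is a switch
  (`stat = "mean"`).
* **"Amplitude" of the peripheral signal.** The default is the
  highpass-filtered signal value (`amp_type = "filtered"`). The Hilbert
  envelope is available (`amp_type = "envelope"`), but note that for a
  peripheral fluctuation that is itself an in-band oscillation locked to
  the EEG phase, the envelope is nearly constant by construction and
  carries no phase information -- under the package's own generative
  model only the filtered-value variant can recover the designed
  preferred phase, which is why it is the default.
* **Standard deviation** is the sample (n-1) estimate; the population
  variant is a switch. The t-test is Welch by default.
* **The per-channel t-test is anti-conservative twice over**: the 1 Hz
  samples are autocorrelated (the effective sample size is far below the
  nominal count), and the tested bins were selected for extremity. The
  test suite measures the null false-positive rate (~0.4 at
  $\alpha = 0.05$ under no coupling) and reports it rather than
  pretending calibration. Per-channel significance at uncorrected
  $\alpha$ reproduces the field's reporting convention; pass the
  p-values through `p.adjust()` where calibrated error control matters.

Per subject, `subject_summary()` aggregates channels: the fraction of
significant channels, the mean d-prime, the circular mean of the
per-channel preferred phases, and their resultant length (the
inter-channel coherence of preferred phases). An antipodal tie (resultant
below $10^{-9}$) makes the circular mean an explicit error rather than an
arbitrary angle.

## Coherence statistics

For phases $\theta_n$ the mean-resultant coherence is
$\left|N^{-1}\sum_n e^{i\theta_n}\right| \in [0, 1]$ -- over channels
(inter-channel phase coherence, ICPC) or over trials at a fixed
post-onset time (inter-trial phase coherence, ITPC). Trials are the
first 30 s after each onset, sampled at 1 Hz (31 time points, 0-30 s
inclusive).

**Permutation null for ITPC.** Each pseudo-ITPC draws $N$ phases
uniformly with replacement from all valid time points of the recording
and applies the same statistic; $10^4$ permutations by default, p-values
with the +1 correction so they are never zero. This randomizes trial
timing while keeping the recording's phase statistics.

**Lag scan.** A single-series resultant cannot depend on a time shift,
so coherence between EEG and a peripheral signal is the mean resultant
of the *phase difference* series
$\theta_{\mathrm{eeg}}(t) - \theta_{\mathrm{per}}(t + \ell)$ (the
standard two-signal phase-locking value), scanned over lags
$\ell \in [-60, 60]$ s in 1 s steps. Positive lag means the peripheral
signal trails the EEG.

**Lag-scan null.** Infraslow phase series are strongly autocorrelated
(coherence times of minutes), so a null that draws phases i.i.d.
uniformly on the circle wildly understates the best-lag coherence two
*independent but smooth* series can reach: in simulation its 95% level
sits near the 10th percentile of genuinely independent session pairs.
The package's default surrogate (`surrogate = "shift"`) instead rotates
the target series circularly by a random offset far outside the lag
grid, preserving its autocorrelation while destroying cross-alignment;
the i.i.d.-uniform variant is retained for comparison with conventions
that use it. The shift surrogate is itself mildly liberal for a
max-over-lags statistic (the splice discontinuity and the suppression of
between-realization variability cost a few percent of coverage:
measured, about 85% of independent session pairs fall below the shift
null's 95% level, versus 10% for the uniform null). Where a generative
model of the signals exists -- as in every synthetic study here -- the
cleanest null is model-based: the best-lag coherence distribution over
independent simulated pairs, which is what the package's own acceptance
checks use. For real recordings the shift surrogate is the best
series-level option provided, and its residual liberality should be kept
in mind near the threshold.

## Group machinery

Subjects are split at the median of a scalar criterion (conventionally
the channel-average d-prime): ranked by value, ties broken by subject
id, top half versus bottom half, so 24 subjects give the conventional
12/12 split. Per-time-point group comparisons pool subject x channel
values as samples (matching the n = 12 x 64 = 768 convention of
full-montage studies; channels are thereby treated as independent, which
overstates the degrees of freedom -- a subject-level variant is simply
the same call on channel-averaged rows). The ITPC group test is
two-sided; the instantaneous-frequency test against the first-10-s
baseline is one-sided (decrease), unpaired by default with a paired
switch. GSR epoch traces use the same epoch machinery with mean and
standard error summaries only.

## The synthetic generator

`gen_session()` draws sessions with the statistical structure the
analysis assumes, and returns the generating truth alongside:

* a master oscillation phase $\varphi(t)$ whose instantaneous frequency
  performs a reflected Gaussian random walk in [0.01, 0.1] Hz around
  `f0 = 0.05` Hz (`freq_jitter_sd = 0.001` Hz s^-1/2 -- enough drift
  that phase alignment between independent sessions decorrelates over
  minutes, which is also what makes the lag scan identifiable instead of
  periodic-aliased);
* EEG channel $c$: `pink_amp` x unit-variance 1/f background (PSD
  $\propto f^{-1}$; Fourier-synthesized) + `isa_amp` $\times
  \cos(\varphi(t) + \delta_c)$ with per-channel offsets $\delta_c$ of
  wrapped-normal spread `channel_phase_sd` (the knob that sets
  achievable inter-channel coherence);
* GSR: a positive baseline + $m \cos(\varphi(t - \ell_{\mathrm{gsr}}) -
  \varphi_{\mathrm{pref}})$ + white noise (`gsr_noise_sd`); respiration
  identical at `resp_lag = 10` s. Skin conductance is physically
  nonnegative, hence the dominant baseline;
* about 41 trials of 30-90 s separated by 20-60 s pauses; at each onset
  the phase is redrawn toward a fixed angle from a von Mises with
  concentration `reset_kappa` (0 = no reset; this is the simplest
  mechanism producing onset-locked ITPC, with no claim to physiology).

Defaults (two hours, 64 channels, `m = 0.5` against `gsr_noise_sd =
0.1`) are the package's standing study conditions. The designed group
study used by the end-to-end checks builds 12 "coupled" subjects with
`m = 1, reset_kappa = 4` against 12 "uncoupled" subjects with
`m = 0, reset_kappa = 0`: depth drives the d-prime median split and the
onset reset drives the group ITPC difference, mirroring the empirical
association between strong peripheral coupling and strong onset phase
locking rather than deriving it. Tests and the
acceptance script run the same model at the 1 Hz analysis rate with one
to four EEG channels -- statistically equivalent for every 1 Hz statistic
and two orders of magnitude cheaper; full-rate (256 Hz) behavior is
covered by the shorter filter/Hilbert fidelity tests. With `isa_amp = 2`
over unit background the oscillation is visible in the band but the
spectral log-log linearity contract is asserted for the background alone
(`isa_amp = 0`), since a visible spectral bump is precisely what a large
oscillation adds.

What the generator does *not* emulate: realistic scalp topography,
artifacts (the band filter removes most), skin-conductance response
kernel shapes, or any nonstationarity beyond the frequency walk and
onset resets. Passing tests therefore demonstrate that the statistics
recover designed structure of this model class, not that real recordings
contain such structure.

The frequency walk's stationary mean under reflection is the band
center, not `f0`; unbiasedness of recovered frequency holds in the
regime where reflections are rare, and the test asserts it there.

## Numerical choices

* Phases are always wrapped to $(-\pi, \pi]$ (the right end closed);
  bins are left-closed with the last bin including $\pi$; bin indices
  are 1-based, so phase 0 falls in bin 5 of 8.
* $d'$ with both spreads zero is 0 for equal means and $+\infty$ (with a
  warning) otherwise; an empty phase bin is an error naming the bin.
* Extreme-bin and best-lag ties resolve to the first index -- deterministic
  given the input.
* The permutation p-value is $(1 + \#\{\mathrm{null} \ge
  \mathrm{obs}\})/(1 + n_{\mathrm{perm}})$.
* EDF stores 16-bit integers (BDF 24-bit) with a per-channel symmetric
  physical range padded 5% above the data maximum, so round-trip error
  is bounded by half a quantization step; header number fields are
  formatted to parse back exactly.
* All stochastic components (generator, permutation draws, surrogates,
  tie-break) take explicit integer seeds and are bit-reproducible.

## Worked example

```{r, eval = FALSE}
cfg <- synthetic_config(duration = 7200, fs = 1, n_eeg = 8,
                        m = 1, phi_pref = pi / 3, seed = 1)
sess <- gen_session(cfg)
pp <- preprocess_recording(sess$recording)
res <- pac_subject(pp)                     # per-channel coupling
subject_summary(res)                       # subject aggregate
ep <- extract_epochs(pp$phase[1, ], pp$trial_onsets, 30)
it <- itpc_timecourse(ep)                  # onset phase locking
nul <- itpc_null(pp$phase[1, ], it$n_trials, seed = 2)
itpc_pvalue(nul, it$itpc)                  # per-time-point p-values
lag_scan(pp$phase[1, pp$valid],
         pp$phase[channels_of(pp, "RESP"), pp$valid],
         n_null = 200, seed = 3)           # optimal peripheral lag
```

## Known limitations

* Real BDF recordings must currently share one sampling rate across
  signals (true for the intended BioSemi sessions); mixed-rate EDF files
  are rejected.
* The per-channel coupling t-test inherits the field's conventions and
  is not calibrated (see above); treat per-channel significance as
  descriptive.
* The generator's inter-channel phase structure is a single
  wrapped-normal scatter knob, not an estimate of any real montage's
  coherence structure.
* Epochs are aligned by rounding onsets to the nearest analysis-rate
  sample; sub-second onset precision is irrelevant at 1 Hz but would
  matter at higher analysis rates.
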