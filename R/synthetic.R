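# Ground-truth session generator. The generative model mirrors the
# statistical structure the analysis assumes: every EEG channel is 1/f
# background plus a shared quasi-periodic infraslow oscillation (a common
# phase trajectory with a per-channel wrapped-normal offset); the GSR is a
# positive baseline whose in-band fluctuation is a cosine of the lagged
# oscillation phase relative to a subject-specific preferred phase, plus
# white noise; respiration is built the same way at a longer lag; trial
# onsets partially reset the oscillation phase via a von Mises redraw.

#' Configuration of the synthetic session generator
#'
#' Defaults describe a two-hour session with a 0.05 Hz quasi-periodic
#' infraslow oscillation shared across 64 EEG channels over a 1/f
#' background, zero-lag GSR coupling and a 10-s-delayed respiration, and
#' about 41 trials of 30-90 s. Tests and desk-scale analyses typically
#' override `fs` to the 1 Hz analysis rate and shrink `n_eeg`.
#'
#' @param duration Session length in seconds (>= 10 / f0).
#' @param fs Sampling rate in Hz.
#' @param n_eeg Number of EEG channels.
#' @param f0 Oscillation center frequency in Hz.
#' @param freq_jitter_sd Random-walk scale of the instantaneous frequency
#'   in Hz per sqrt(second); the walk is reflected at `freq_range`.
#' @param freq_range Reflection bounds of the instantaneous frequency (Hz).
#' @param isa_amp Oscillation amplitude in EEG channels (a.u.).
#' @param pink_slope Background spectral exponent (PSD proportional to
#'   f^slope).
#' @param pink_amp Background amplitude scale (a.u., unit-variance noise
#'   times this).
#' @param phi_pref Preferred coupling phase (radians): the oscillation
#'   phase at which the GSR fluctuation is maximal.
#' @param m Coupling depth: amplitude of the phase-locked GSR/respiration
#'   fluctuation (same units as the signals; 0 = no coupling).
#' @param gsr_noise_sd White-noise s.d. added to GSR and respiration.
#' @param gsr_lag,resp_lag Delay of the peripheral signal relative to the
#'   EEG oscillation, in seconds (positive = peripheral lags EEG).
#' @param gsr_baseline,resp_baseline Constant offsets keeping the signals
#'   positive (skin conductance is physically nonnegative).
#' @param n_trials Maximal number of trials; fewer are generated if the
#'   session is too short.
#' @param trial_len_range,iti_range Uniform ranges (seconds) for trial
#'   lengths and inter-trial intervals.
#' @param reset_phase Phase toward which trial onsets reset the
#'   oscillation (radians).
#' @param reset_kappa von Mises concentration of the onset phase reset:
#'   0 = no reset at all, large = near-exact reset.
#' @param channel_phase_sd Wrapped-normal s.d. (radians) of per-channel
#'   phase offsets; controls the achievable inter-channel coherence.
#' @param seed Integer seed; identical configurations generate
#'   bit-identical sessions.
#' @return Validated list of class `synthetic_config`.
#' @export
synthetic_config <- function(duration = 7200, fs = 256, n_eeg = 64,
                             f0 = 0.05, freq_jitter_sd = 0.001,
                             freq_range = c(0.01, 0.1),
                             isa_amp = 2, pink_slope = -1, pink_amp = 1,
                             phi_pref = 0, m = 0.5, gsr_noise_sd = 0.1,
                             gsr_lag = 0, resp_lag = 10,
                             gsr_baseline = 10, resp_baseline = 5,
                             n_trials = 41,
                             trial_len_range = c(30, 90),
                             iti_range = c(20, 60),
                             reset_phase = 0, reset_kappa = 2,
                             channel_phase_sd = 1, seed = 1) {
  cfg <- as.list(environment())
  bad <- character(0)
  if (!(duration >= 10 / f0)) bad <- c(bad, "duration (need >= 10 / f0)")
  if (!(fs > 0)) bad <- c(bad, "fs (need > 0)")
  if (!(n_eeg >= 1)) bad <- c(bad, "n_eeg (need >= 1)")
  if (!(f0 > 0 && f0 < fs / 2)) bad <- c(bad, "f0 (need 0 < f0 < fs/2)")
  if (!(freq_range[1] > 0 && freq_range[2] > freq_range[1] &&
        f0 >= freq_range[1] && f0 <= freq_range[2]))
    bad <- c(bad, "freq_range (need 0 < lo <= f0 <= hi)")
  if (m < 0) bad <- c(bad, "m (need >= 0)")
  for (f in c("freq_jitter_sd", "isa_amp", "pink_amp", "gsr_noise_sd",
              "reset_kappa", "channel_phase_sd"))
    if (cfg[[f]] < 0) bad <- c(bad, paste0(f, " (need >= 0)"))
  if (length(bad))
    stop("invalid synthetic_config field(s): ", paste(bad, collapse = "; "))
  structure(cfg, class = "synthetic_config")
}

#' Fourier-synthesized power-law (pink) noise
#'
#' Gaussian noise whose power spectral density is proportional to
#' f^`slope` (so the magnitude spectrum goes as f^(slope/2); `slope = 0`
#' is white, `slope = -1` the classic pink spectrum). Output is
#' standardized to zero mean and unit standard deviation.
#'
#' @param n Number of samples (>= 16).
#' @param fs Sampling rate in Hz.
#' @param slope Spectral exponent of the PSD.
#' @param seed Optional seed (NULL draws from the ambient RNG stream).
#' @return Numeric series of length `n`.
#' @export
gen_pink_noise <- function(n, fs = 1, slope = -1, seed = NULL) {
  if (n < 16L) stop("gen_pink_noise: need n >= 16")
  with_seed(seed, {
    nh <- n %/% 2L
    f <- (1:nh) * fs / n
    amp <- f^(slope / 2)
    re <- stats::rnorm(nh) * amp
    im <- stats::rnorm(nh) * amp
    spec <- complex(real = re, imaginary = im)
    if (n %% 2L == 0L) spec[nh] <- complex(real = re[nh], imaginary = 0)
    full <- c(0, spec,
              if (n %% 2L == 0L) Conj(rev(spec[-nh])) else Conj(rev(spec)))
    x <- Re(stats::fft(full, inverse = TRUE)) / n
    as.numeric(scale(x))
  })
}

reflect_into <- function(x, lo, hi) {
  w <- hi - lo
  y <- (x - lo) %% (2 * w)
  lo + ifelse(y > w, 2 * w - y, y)
}

#' Quasi-periodic oscillation phase trajectory
#'
#' The instantaneous frequency performs a Gaussian random walk around
#' `f0`, reflected at `freq_range`; the phase is its integral (plus a
#' uniform random start phase).
#'
#' @inheritParams synthetic_config
#' @param seed Optional seed (NULL draws from the ambient stream).
#' @return List with `phase` (wrapped, (-pi, pi]), `freq` (Hz, within
#'   `freq_range`) and `fs`.
#' @export
gen_isa_phase <- function(duration, fs = 1, f0 = 0.05,
                          freq_jitter_sd = 0.001,
                          freq_range = c(0.01, 0.1), seed = NULL) {
  if (f0 <= 0 || f0 >= fs / 2) stop("gen_isa_phase: need 0 < f0 < fs/2")
  n <- as.integer(round(duration * fs))
  with_seed(seed, {
    dt <- 1 / fs
    walk <- f0 + cumsum(c(0, stats::rnorm(n - 1L, 0, freq_jitter_sd * sqrt(dt))))
    freq <- reflect_into(walk, freq_range[1], freq_range[2])
    phi0 <- stats::runif(1, -pi, pi)
    phase <- phi0 + 2 * pi * cumsum(freq) * dt
    list(phase = wrap_phase(phase), freq = freq, fs = fs,
         unwrapped = phase)
  })
}

draw_trial_onsets <- function(cfg) {
  onsets <- numeric(0)
  lens <- numeric(0)
  t0 <- 120 + stats::runif(1, cfg$iti_range[1], cfg$iti_range[2])
  horizon <- cfg$duration - 60
  while (length(onsets) < cfg$n_trials) {
    len <- stats::runif(1, cfg$trial_len_range[1], cfg$trial_len_range[2])
    if (t0 + len > horizon) break
    onsets <- c(onsets, t0)
    lens <- c(lens, len)
    t0 <- t0 + len + stats::runif(1, cfg$iti_range[1], cfg$iti_range[2])
  }
  list(onsets = round(onsets), lens = round(lens))
}

#' Generate a synthetic session with ground truth
#'
#' Draws a full multichannel recording under the generative model of
#' [synthetic_config()] and returns it together with the ground truth a
#' test needs to score recovery: the true oscillation phase at every
#' sample, the per-channel phase offsets, the instantaneous-frequency
#' trajectory and the trial onsets.
#'
#' @param cfg A [synthetic_config()].
#' @return List with `recording` (an [recording()] with channels
#'   EEG01..EEGnn, GSR, RESP) and `truth` (list: `phase`, `freq`,
#'   `delta` per EEG channel, `onsets`, `trial_lens`, `config`).
#' @export
gen_session <- function(cfg) {
  stopifnot(inherits(cfg, "synthetic_config"))
  fs <- cfg$fs
  n <- as.integer(round(cfg$duration * fs))
  pad <- as.integer(ceiling(max(abs(c(cfg$gsr_lag, cfg$resp_lag, 0))) * fs))
  core <- (pad + 1L):(pad + n)

  with_seed(cfg$seed, {
    osc <- gen_isa_phase((n + 2L * pad) / fs, fs, cfg$f0,
                         cfg$freq_jitter_sd, cfg$freq_range, seed = NULL)
    phi <- osc$unwrapped
    tr <- draw_trial_onsets(cfg)
    if (cfg$reset_kappa > 0) {
      for (on in tr$onsets) {
        i0 <- pad + as.integer(round(on * fs)) + 1L
        target <- rvonmises(1L, cfg$reset_phase, cfg$reset_kappa)
        phi[i0:length(phi)] <- phi[i0:length(phi)] +
          wrap_phase(target - wrap_phase(phi[i0]))
      }
    }

    delta <- wrap_phase(stats::rnorm(cfg$n_eeg, 0, cfg$channel_phase_sd))
    data <- matrix(0, cfg$n_eeg + 2L, n)
    for (ch in seq_len(cfg$n_eeg)) {
      data[ch, ] <- cfg$pink_amp * gen_pink_noise(n, fs, cfg$pink_slope) +
        cfg$isa_amp * cos(phi[core] + delta[ch])
    }
    gsr_idx <- core - as.integer(round(cfg$gsr_lag * fs))
    resp_idx <- core - as.integer(round(cfg$resp_lag * fs))
    data[cfg$n_eeg + 1L, ] <- cfg$gsr_baseline +
      cfg$m * cos(phi[gsr_idx] - cfg$phi_pref) +
      cfg$gsr_noise_sd * stats::rnorm(n)
    data[cfg$n_eeg + 2L, ] <- cfg$resp_baseline +
      cfg$m * cos(phi[resp_idx] - cfg$phi_pref) +
      cfg$gsr_noise_sd * stats::rnorm(n)

    labels <- c(sprintf("EEG%02d", seq_len(cfg$n_eeg)), "GSR", "RESP")
    rec <- recording(data, fs, labels,
                     c(rep("EEG", cfg$n_eeg), "GSR", "RESP"),
                     trial_onsets = tr$onsets,
                     subject_id = paste0("synth-seed", cfg$seed))
    list(recording = rec,
         truth = list(phase = wrap_phase(phi[core]), freq = osc$freq[core],
                      delta = delta, onsets = tr$onsets,
                      trial_lens = tr$lens, config = cfg))
  })
}
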