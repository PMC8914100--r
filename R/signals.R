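# Preprocessing chain for infraslow analysis: zero-phase Butterworth
# filtering at the native rate, FFT-based analytic signal, instantaneous
# frequency from the unwrapped phase, then decimation to the analysis rate
# (1 Hz by default). The order -- filter and Hilbert at the native rate,
# downsample last -- is deliberate and pinned by a regression test.

check_filter_length <- function(n, fs, low_edge, what) {
  n_min <- ceiling(3 * fs / low_edge)
  if (n < n_min)
    stop(what, ": series too short for stable filtering at ", low_edge,
         " Hz; need at least ", n_min, " samples (3 time constants), got ", n)
}

#' Zero-phase infraslow bandpass filter
#'
#' Butterworth bandpass (order `order` per pass, applied forward and
#' backward with [signal::filtfilt()], so the effective order is doubled
#' and the phase response is zero). Defaults select the 0.01-0.1 Hz
#' infraslow band.
#'
#' @param x Numeric series.
#' @param fs Sampling rate in Hz; must exceed `2 * high`.
#' @param low,high Band edges in Hz.
#' @param order Butterworth order per pass.
#' @return Filtered series, same length as `x`.
#' @export
bandpass_isa <- function(x, fs, low = 0.01, high = 0.1, order = 2) {
  if (fs <= 2 * high)
    stop("bandpass_isa: fs (", fs, ") must exceed 2*high (", 2 * high, ")")
  if (low <= 0 || high <= low) stop("bandpass_isa: need 0 < low < high")
  check_filter_length(length(x), fs, low, "bandpass_isa")
  bf <- signal::butter(order, c(low, high) / (fs / 2), type = "pass")
  as.numeric(signal::filtfilt(bf, x))
}

#' Zero-phase highpass filter for drift removal
#'
#' Used on peripheral channels (GSR, respiration) to remove slow drifts
#' below the infraslow band.
#'
#' @inheritParams bandpass_isa
#' @param cutoff Cutoff frequency in Hz.
#' @return Filtered series, same length as `x`.
#' @export
highpass <- function(x, fs, cutoff = 0.01, order = 2) {
  if (cutoff <= 0 || cutoff >= fs / 2)
    stop("highpass: cutoff must lie in (0, fs/2)")
  check_filter_length(length(x), fs, cutoff, "highpass")
  bf <- signal::butter(order, cutoff / (fs / 2), type = "high")
  as.numeric(signal::filtfilt(bf, x))
}

#' Analytic signal: instantaneous phase and amplitude envelope
#'
#' Computes the analytic extension of a (band-limited) real series via the
#' FFT one-sided-spectrum method and returns its argument (phase, wrapped
#' into (-pi, pi]) and modulus (envelope). Because the Hilbert transform is
#' global, a guard window at each end of the series is flagged unreliable
#' (`valid = FALSE`); statistics downstream exclude those samples by
#' default. At infraslow frequencies edge transients are long, hence the
#' generous 100-s default.
#'
#' @param x Real series, already filtered to the band of interest.
#' @param fs Sampling rate in Hz.
#' @param source_band Optional c(low, high) Hz annotation.
#' @param edge_guard Guard length in seconds flagged at each end.
#' @return An object of class `analytic_series`: list with `phase`,
#'   `amplitude`, `fs`, `source_band`, `valid`.
#' @export
analytic <- function(x, fs, source_band = NULL, edge_guard = 100) {
  n <- length(x)
  if (n < 2L) stop("analytic: series too short")
  if (all(x == 0)) stop("analytic: all-zero input, phase undefined")
  h <- numeric(n)
  if (n %% 2L == 0L) {
    h[c(1L, n / 2L + 1L)] <- 1
    h[2L:(n / 2L)] <- 2
  } else {
    h[1L] <- 1
    h[2L:((n + 1L) / 2L)] <- 2
  }
  z <- stats::fft(stats::fft(x) * h, inverse = TRUE) / n
  g <- min(floor(edge_guard * fs), max(floor((n - 1L) / 2L), 0L))
  valid <- rep(TRUE, n)
  if (g > 0L) valid[c(seq_len(g), n - seq_len(g) + 1L)] <- FALSE
  structure(list(phase = wrap_phase(Arg(z)), amplitude = Mod(z), fs = fs,
                 source_band = source_band, valid = valid),
            class = "analytic_series")
}

#' @export
print.analytic_series <- function(x, ...) {
  cat(sprintf("<analytic_series> %d samples @ %g Hz, %d flagged unreliable\n",
              length(x$phase), x$fs, sum(!x$valid)))
  invisible(x)
}

# unwrap a phase series (cumulative wrapped first differences)
unwrap_phase <- function(phase)
  phase[1L] + c(0, cumsum(wrap_phase(diff(phase))))

#' Instantaneous frequency from an analytic phase
#'
#' The phase is unwrapped, then differentiated with central finite
#' differences (one-sided at the endpoints) and scaled by 1/(2*pi).
#'
#' @param x An `analytic_series`, or a numeric phase series (radians).
#' @param ... Passed on to methods.
#' @return Numeric series of frequencies in Hz, same length as the phase.
#' @export
instantaneous_frequency <- function(x, ...) UseMethod("instantaneous_frequency")

#' @rdname instantaneous_frequency
#' @export
instantaneous_frequency.analytic_series <- function(x, ...)
  instantaneous_frequency(x$phase, fs = x$fs)

#' @rdname instantaneous_frequency
#' @param fs Sampling rate in Hz (default method only).
#' @export
instantaneous_frequency.default <- function(x, fs, ...) {
  n <- length(x)
  if (n < 2L) stop("instantaneous_frequency: need at least 2 samples")
  uw <- unwrap_phase(x)
  f <- numeric(n)
  f[1L] <- (uw[2L] - uw[1L]) * fs
  f[n] <- (uw[n] - uw[n - 1L]) * fs
  if (n > 2L) f[2L:(n - 1L)] <- (uw[3L:n] - uw[1L:(n - 2L)]) * fs / 2
  f / (2 * pi)
}

#' Downsample a series by integer decimation
#'
#' Plain decimation: the input is assumed already band-limited well below
#' the output Nyquist frequency (true for the 0.01-0.1 Hz band at a 1 Hz
#' output rate), so no additional anti-alias filter is applied. Applied
#' after filtering and Hilbert transformation, never before.
#'
#' @param x Numeric series or `analytic_series`.
#' @param ... Passed on to methods.
#' @return Same type as the input, at the new rate.
#' @export
downsample <- function(x, ...) UseMethod("downsample")

decimation_idx <- function(n, fs_in, fs_out) {
  r <- fs_in / fs_out
  if (abs(r - round(r)) > 1e-9)
    stop("downsample: fs_in/fs_out must be an integer ratio (got ", r, ")")
  seq.int(1L, n, by = as.integer(round(r)))
}

#' @rdname downsample
#' @param fs_in,fs_out Input and output sampling rates in Hz; the ratio
#'   must be an integer.
#' @export
downsample.default <- function(x, fs_in, fs_out = 1, ...)
  x[decimation_idx(length(x), fs_in, fs_out)]

#' @rdname downsample
#' @export
downsample.analytic_series <- function(x, fs_out = 1, ...) {
  idx <- decimation_idx(length(x$phase), x$fs, fs_out)
  structure(list(phase = x$phase[idx], amplitude = x$amplitude[idx],
                 fs = fs_out, source_band = x$source_band,
                 valid = x$valid[idx]),
            class = "analytic_series")
}

#' FFT magnitude spectrum
#'
#' Absolute values of the discrete Fourier transform at the nonnegative
#' frequencies.
#'
#' @param x Numeric series.
#' @param fs Sampling rate in Hz.
#' @return Object of class `isa_spectrum`: list with ascending `freqs`
#'   (Hz) and nonnegative `magnitude`.
#' @export
magnitude_spectrum <- function(x, fs) {
  n <- length(x)
  if (n == 0L) stop("magnitude_spectrum: empty series")
  if (any(!is.finite(x))) stop("magnitude_spectrum: non-finite samples")
  k <- 0:(n %/% 2L)
  structure(list(freqs = k * fs / n, magnitude = Mod(stats::fft(x))[k + 1L]),
            class = "isa_spectrum")
}

#' Log-log spectral slope over a frequency band
#'
#' Least-squares slope of log10(magnitude) against log10(frequency),
#' restricted to `band`. Used to check 1/f-type spectra.
#'
#' @param spec An `isa_spectrum`.
#' @param band c(low, high) Hz.
#' @return Fitted slope (dimensionless).
#' @export
loglog_slope <- function(spec, band = c(0.01, 0.1)) {
  sel <- spec$freqs >= band[1] & spec$freqs <= band[2] &
    spec$freqs > 0 & spec$magnitude > 0
  if (sum(sel) < 3L) stop("loglog_slope: fewer than 3 usable frequencies in band")
  unname(stats::coef(stats::lm(log10(spec$magnitude[sel]) ~
                                 log10(spec$freqs[sel])))[2L])
}

#' Preprocess a recording for infraslow analysis
#'
#' For each EEG channel: bandpass to `c(low, high)`, analytic signal, and
#' instantaneous frequency, all at the native rate. For GSR/respiration
#' channels: highpass at `low` and analytic signal. Everything is then
#' decimated to `out_rate`. The filtered (pre-Hilbert) series is kept
#' alongside phase and envelope so either can serve as the "amplitude" of
#' a peripheral signal.
#'
#' @param rec An [recording()] object.
#' @param low,high Infraslow band edges in Hz; `low` is also the highpass
#'   cutoff for peripheral channels.
#' @param out_rate Analysis sampling rate in Hz.
#' @param edge_guard Seconds flagged unreliable at each end.
#' @param order Butterworth order per pass.
#' @return Object of class `isa_preprocessed`: matrices `phase`,
#'   `amplitude`, `filtered`, `ifreq` (channels x output samples; `ifreq`
#'   is NA for non-EEG channels), logical `valid`, plus channel metadata,
#'   `trial_onsets` and the parameter list.
#' @export
preprocess_recording <- function(rec, low = 0.01, high = 0.1, out_rate = 1,
                                 edge_guard = 100, order = 2) {
  stopifnot(inherits(rec, "isa_recording"))
  n <- ncol(rec$data)
  idx <- decimation_idx(n, rec$fs, out_rate)
  nch <- nrow(rec$data)
  n_out <- length(idx)
  phase <- amplitude <- filtered <- ifreq <-
    matrix(NA_real_, nch, n_out,
           dimnames = list(rec$channel_labels, NULL))
  valid <- rep(TRUE, n_out)
  for (ch in seq_len(nch)) {
    x <- rec$data[ch, ]
    if (rec$modality[ch] == "EEG") {
      f <- bandpass_isa(x, rec$fs, low = low, high = high, order = order)
      a <- analytic(f, rec$fs, source_band = c(low, high),
                    edge_guard = edge_guard)
      ifreq[ch, ] <- instantaneous_frequency(a)[idx]
    } else {
      f <- highpass(x, rec$fs, cutoff = low, order = order)
      a <- analytic(f, rec$fs, source_band = c(low, NA),
                    edge_guard = edge_guard)
    }
    phase[ch, ] <- a$phase[idx]
    amplitude[ch, ] <- a$amplitude[idx]
    filtered[ch, ] <- f[idx]
    valid <- valid & a$valid[idx]
  }
  structure(
    list(phase = phase, amplitude = amplitude, filtered = filtered,
         ifreq = ifreq, valid = valid, fs = out_rate,
         channel_labels = rec$channel_labels, modality = rec$modality,
         trial_onsets = rec$trial_onsets, subject_id = rec$subject_id,
         group_label = rec$group_label,
         params = list(low = low, high = high, out_rate = out_rate,
                       edge_guard = edge_guard, order = order,
                       fs_in = rec$fs)),
    class = "isa_preprocessed")
}

#' @export
print.isa_preprocessed <- function(x, ...) {
  cat(sprintf("<isa_preprocessed> subject '%s': %d channels x %d samples @ %g Hz\n",
              x$subject_id, nrow(x$phase), ncol(x$phase), x$fs))
  cat(sprintf("  band %g-%g Hz, edge guard %g s (%d samples excluded), %d onsets\n",
              x$params$low, x$params$high, x$params$edge_guard,
              sum(!x$valid), length(x$trial_onsets)))
  invisible(x)
}
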