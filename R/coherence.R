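# Phase-coherence statistics. ICPC and ITPC are the same quantity -- the
# modulus of the mean unit phasor |N^-1 sum exp(i theta_n)| -- applied over
# channels (ICPC) or over trials at a fixed post-onset time (ITPC). The
# ITPC permutation null draws phases from pseudo-random time points of the
# whole recording; the lag scan applies the two-signal analogue (mean
# resultant of the phase-difference series) over a grid of time shifts.

#' Inter-channel phase coherence (mean resultant length)
#'
#' @param phases Phases in radians (one per channel, or per trial).
#' @return Value in [0, 1]: 0 = fully dispersed, 1 = all aligned.
#' @export
icpc <- function(phases) {
  if (length(phases) == 0L) stop("icpc: empty phase vector")
  if (any(!is.finite(phases))) stop("icpc: non-finite phases")
  min(Mod(mean(exp(1i * phases))), 1)
}

#' Inter-trial phase coherence time course
#'
#' Applies the mean-resultant statistic independently at each post-onset
#' time point, across trials.
#'
#' @param trial_phases Matrix, trials x time points (rows from
#'   [extract_epochs()] applied to a phase series), or an `epoch_set`.
#' @param fs Sampling rate of the epoch time axis in Hz.
#' @return Object of class `itpc_series`: `t` (seconds from onset),
#'   `itpc` in [0, 1] per time point, `n_trials`.
#' @export
itpc_timecourse <- function(trial_phases, fs = 1) {
  tax <- attr(trial_phases, "t")
  trial_phases <- unclass(as.matrix(trial_phases))
  if (nrow(trial_phases) < 2L)
    stop("itpc_timecourse: need at least 2 trials")
  if (is.null(tax)) tax <- (seq_len(ncol(trial_phases)) - 1L) / fs
  vals <- apply(trial_phases, 2L, icpc)
  structure(list(t = tax, itpc = unname(vals),
                 n_trials = nrow(trial_phases)),
            class = "itpc_series")
}

#' @export
print.itpc_series <- function(x, ...) {
  cat(sprintf("<itpc_series> %d trials, t = %g..%g s, ITPC %.3f..%.3f\n",
              x$n_trials, min(x$t), max(x$t), min(x$itpc), max(x$itpc)))
  invisible(x)
}

#' Permutation null distribution for ITPC
#'
#' Each pseudo-ITPC is the mean-resultant statistic over `n_trials` phases
#' drawn uniformly (with replacement) from the valid time points of the
#' whole recording's phase series -- i.e. trial timing is randomized while
#' the phase statistics of the recording are kept. The empirical p-value
#' uses the +1 correction so it is never zero.
#'
#' @param phase_series Full-recording phase series (radians) for one
#'   channel; NA values (e.g. edge-guarded samples set to NA) are
#'   excluded.
#' @param n_trials The N of the observed ITPC.
#' @param n_perm Number of permutations (default 10000).
#' @param seed Integer seed; same seed, same inputs give a bit-identical
#'   null.
#' @return Object of class `itpc_null` with the sorted `values`,
#'   `n_perm`, `n_trials`, `seed`.
#' @export
itpc_null <- function(phase_series, n_trials, n_perm = 10000, seed = NULL) {
  pool <- phase_series[is.finite(phase_series)]
  if (length(pool) < n_trials)
    stop("itpc_null: recording too short for ", n_trials, " draws")
  if (n_perm < 100) warning("itpc_null: n_perm < 100 gives unstable tail estimates")
  vals <- with_seed(seed, {
    draws <- matrix(sample(pool, n_perm * n_trials, replace = TRUE),
                    nrow = n_perm)
    Mod(rowMeans(exp(1i * draws)))
  })
  structure(list(values = sort(vals), n_perm = as.integer(n_perm),
                 n_trials = as.integer(n_trials), seed = seed),
            class = "itpc_null")
}

#' Permutation p-value(s) against an ITPC null
#'
#' `p = (1 + #\{null >= observed\}) / (1 + n_perm)`.
#'
#' @param null An [itpc_null()].
#' @param observed Observed ITPC value(s).
#' @return p-values in (0, 1], same length as `observed`.
#' @export
itpc_pvalue <- function(null, observed) {
  stopifnot(inherits(null, "itpc_null"))
  n_ge <- null$n_perm -
    findInterval(observed, null$values, left.open = TRUE)
  (1 + n_ge) / (1 + null$n_perm)
}

#' Null quantile of an ITPC permutation distribution
#'
#' @param null An [itpc_null()].
#' @param probs Quantile probabilities (default 0.95).
#' @return Quantile(s) of the pseudo-ITPC distribution.
#' @export
itpc_null_quantile <- function(null, probs = 0.95)
  stats::quantile(null$values, probs, names = FALSE)

# phase-difference coherence for a vector of integer sample shifts
phase_diff_icpc <- function(z1, z2, shifts, min_overlap) {
  n <- length(z1)
  vapply(shifts, function(s) {
    if (s >= 0) {
      m <- n - s
      if (m < min_overlap) return(NA_real_)
      Mod(mean(z1[seq_len(m)] * Conj(z2[seq_len(m) + s])))
    } else {
      m <- n + s
      if (m < min_overlap) return(NA_real_)
      Mod(mean(z1[seq_len(m) - s] * Conj(z2[seq_len(m)])))
    }
  }, 0)
}

#' Scan time lags for maximal EEG-peripheral phase coherence
#'
#' For each lag the coherence is the mean resultant of the phase
#' difference series `theta_eeg(t) - theta_target(t + lag)` over the
#' overlapping samples (the standard two-signal phase-locking value; a
#' single-series mean resultant cannot depend on lag). Positive lag means
#' the target (peripheral) signal is delayed relative to the EEG. A
#' significance reference is the 95th percentile of best-lag coherences of
#' `n_null` phase-series pairs drawn uniformly on the circle with the same
#' lengths and lag grid ([lag_scan_null()]; set `n_null = 0` to skip and
#' supply a precomputed level).
#'
#' @param eeg_phase,target_phase Phase series in radians at rate `fs`.
#' @param lag_range Maximal absolute lag in seconds (default 60).
#' @param lag_step Lag grid step in seconds (default 1; `lag_step * fs`
#'   must be an integer).
#' @param fs Sampling rate in Hz.
#' @param min_overlap Minimal number of overlapping samples for a lag to
#'   be evaluated; shorter overlaps are dropped with a warning.
#' @param n_null Randomized-phase replicates for the null level (0 = skip).
#' @param seed Seed for the null replicates.
#' @param surrogate Null surrogate type, see [lag_scan_null()].
#' @return Object of class `lag_scan`: `lags` (s), `icpc_by_lag`,
#'   `best_lag`, `best_icpc`, `null95`, `n_null`.
#' @export
lag_scan <- function(eeg_phase, target_phase, lag_range = 60, lag_step = 1,
                     fs = 1, min_overlap = 300, n_null = 1000, seed = NULL,
                     surrogate = c("shift", "uniform")) {
  if (length(eeg_phase) != length(target_phase))
    stop("lag_scan: series must be equal length")
  lags <- seq(-lag_range, lag_range, by = lag_step)
  shifts <- lags * fs
  if (any(abs(shifts - round(shifts)) > 1e-9))
    stop("lag_scan: lag_step * fs must be an integer")
  shifts <- as.integer(round(shifts))
  ok1 <- is.finite(eeg_phase) & is.finite(target_phase)
  if (!all(ok1)) {
    eeg_phase <- eeg_phase[ok1]
    target_phase <- target_phase[ok1]
  }
  z1 <- exp(1i * eeg_phase)
  z2 <- exp(1i * target_phase)
  vals <- phase_diff_icpc(z1, z2, shifts, min_overlap)
  if (anyNA(vals)) {
    warning("lag_scan: ", sum(is.na(vals)),
            " lag(s) dropped (overlap < ", min_overlap, " samples)")
    keep <- !is.na(vals)
    lags <- lags[keep]; vals <- vals[keep]
  }
  if (!length(vals)) stop("lag_scan: no lag with sufficient overlap")
  best <- which.max(vals)
  null95 <- if (n_null > 0)
    lag_scan_null(eeg_phase, target_phase, lag_range = lag_range,
                  lag_step = lag_step, fs = fs, min_overlap = min_overlap,
                  n_null = n_null, seed = seed, surrogate = surrogate)
  else NA_real_
  structure(list(lags = lags, icpc_by_lag = unname(vals),
                 best_lag = lags[best], best_icpc = vals[best],
                 null95 = null95, n_null = n_null),
            class = "lag_scan")
}

#' Randomized-phase null level for the lag scan
#'
#' Each replicate destroys any EEG-target alignment, reruns the same lag
#' grid, and records the best-lag coherence; the returned level is the
#' 95th percentile of those maxima.
#'
#' Two surrogates are available. `"shift"` (default) rotates the target
#' phase series circularly by a random offset far outside the lag grid:
#' this preserves each series' autocorrelation -- smooth oscillation phase
#' has a long coherence time, so far fewer effective degrees of freedom
#' than samples -- and therefore calibrates correctly for real phase
#' series. `"uniform"` draws both series i.i.d. uniform on the circle; it
#' depends only on the series length, but because it ignores
#' autocorrelation it is badly anti-conservative for smooth phases and is
#' provided for comparison only.
#'
#' Since the `"shift"` level reflects the generating process rather than
#' one particular pair, it can be computed once and reused across channels
#' of the same length and dynamics.
#'
#' @param eeg_phase,target_phase Phase series (radians); for
#'   `surrogate = "uniform"` only their length is used.
#' @inheritParams lag_scan
#' @param probs Percentile to return (default 0.95).
#' @return The null level (scalar).
#' @export
lag_scan_null <- function(eeg_phase, target_phase = NULL, lag_range = 60,
                          lag_step = 1, fs = 1, min_overlap = 300,
                          n_null = 1000, seed = NULL,
                          surrogate = c("shift", "uniform"),
                          probs = 0.95) {
  surrogate <- match.arg(surrogate)
  if (length(eeg_phase) == 1L && is.null(target_phase)) {
    # length-only invocation, valid for the uniform surrogate
    if (surrogate != "uniform")
      stop("lag_scan_null: the shift surrogate needs both phase series")
    n <- as.integer(eeg_phase)
  } else {
    ok <- is.finite(eeg_phase) &
      (if (is.null(target_phase)) TRUE else is.finite(target_phase))
    eeg_phase <- eeg_phase[ok]
    if (!is.null(target_phase)) target_phase <- target_phase[ok]
    n <- length(eeg_phase)
  }
  shifts <- as.integer(round(seq(-lag_range, lag_range, by = lag_step) * fs))
  max_shift <- max(abs(shifts))
  if (surrogate == "shift") {
    if (is.null(target_phase))
      stop("lag_scan_null: the shift surrogate needs both phase series")
    z1 <- exp(1i * eeg_phase)
    z2 <- exp(1i * target_phase)
    margin <- max(4L * max_shift, n %/% 8L)
    if (n - 2L * margin < 2L)
      stop("lag_scan_null: series too short for shift surrogates")
  }
  best <- with_seed(seed, {
    vapply(seq_len(n_null), function(i) {
      if (surrogate == "shift") {
        k <- sample(margin:(n - margin), 1L)
        z2r <- c(z2[(k + 1L):n], z2[seq_len(k)])
        max(phase_diff_icpc(z1, z2r, shifts, min_overlap), na.rm = TRUE)
      } else {
        a <- exp(1i * stats::runif(n, -pi, pi))
        b <- exp(1i * stats::runif(n, -pi, pi))
        max(phase_diff_icpc(a, b, shifts, min_overlap), na.rm = TRUE)
      }
    }, 0)
  })
  stats::quantile(best, probs, names = FALSE)
}

#' @export
print.lag_scan <- function(x, ...) {
  cat(sprintf("<lag_scan> best lag %+g s (coherence %.3f) over %d lags; null95 %s\n",
              x$best_lag, x$best_icpc, length(x$lags),
              if (is.na(x$null95)) "not computed" else sprintf("%.3f", x$null95)))
  invisible(x)
}
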