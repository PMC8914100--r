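# Phase-amplitude coupling statistics: the phase circle is divided into
# equal bins, the coupled signal's amplitude is summarized per bin, and the
# bins with maximal and minimal median amplitude are contrasted with a
# d-prime discriminability index and a two-sample t-test.

#' Equal-width partition of the phase circle
#'
#' `n_bins` left-closed intervals covering (-pi, pi]; with the default 8
#' bins the width is pi/4. Bin indices are 1-based: phase 0 falls in bin
#' `n_bins/2 + 1` and phase pi in bin `n_bins`.
#'
#' @param n_bins Number of bins.
#' @return Object of class `phase_binning`: list with `n_bins`, `edges`
#'   (length n_bins + 1) and `centers`.
#' @export
phase_binning <- function(n_bins = 8) {
  if (n_bins < 2L) stop("phase_binning: need at least 2 bins")
  edges <- seq(-pi, pi, length.out = n_bins + 1L)
  structure(list(n_bins = as.integer(n_bins), edges = edges,
                 centers = (edges[-1L] + edges[-(n_bins + 1L)]) / 2),
            class = "phase_binning")
}

#' Map phases to bin indices
#'
#' Bins are left-closed, right-open, except the last which includes pi.
#' Phases outside (-pi, pi] are an error: callers must [wrap_phase()]
#' first.
#'
#' @param theta Phases in radians, each in (-pi, pi].
#' @param binning A [phase_binning()].
#' @return Integer bin indices in 1..n_bins.
#' @export
phase_bin_index <- function(theta, binning = phase_binning()) {
  if (any(theta <= -pi | theta > pi))
    stop("phase_bin_index: phases outside (-pi, pi]; wrap first")
  width <- 2 * pi / binning$n_bins
  pmin.int(floor((theta + pi) / width) + 1L, binning$n_bins)
}

#' d-prime discriminability index between two samples
#'
#' `|mean(x1) - mean(x2)| / ((sd(x1) + sd(x2)) / 2)`. The standard
#' deviation is the sample (n-1 denominator) estimate by default. When
#' both spreads are zero the index is 0 for equal means and +Inf (with a
#' warning) otherwise.
#'
#' @param x1,x2 Numeric samples, each of length >= 2.
#' @param sd_type "sample" (n-1) or "population" (n).
#' @return Nonnegative scalar (possibly +Inf).
#' @export
dprime <- function(x1, x2, sd_type = c("sample", "population")) {
  sd_type <- match.arg(sd_type)
  if (length(x1) < 2L || length(x2) < 2L)
    stop("dprime: each sample needs at least 2 values")
  sdev <- function(v) {
    s <- stats::sd(v)
    if (sd_type == "population") s * sqrt((length(v) - 1) / length(v)) else s
  }
  num <- abs(mean(x1) - mean(x2))
  den <- (sdev(x1) + sdev(x2)) / 2
  if (den == 0) {
    if (num == 0) return(0)
    warning("dprime: zero spread in both samples with unequal means; +Inf")
    return(Inf)
  }
  num / den
}

#' Phase-amplitude coupling statistics for one channel
#'
#' Bins the coupled signal's amplitude samples by the simultaneous EEG
#' infraslow phase, identifies the bins with maximal and minimal median
#' (or mean) amplitude, and contrasts their amplitude distributions with
#' [dprime()] and a two-sample t-test (Welch by default).
#'
#' Note the t-test treats the 1 Hz samples as independent, ignoring their
#' autocorrelation; with hours of data this inflates the effective sample
#' size and makes per-channel p-values anti-conservative. This mirrors the
#' convention of per-channel significance reporting in infraslow coupling
#' work and is kept as the default deliberately.
#'
#' @param eeg_phase Phase series in radians, (-pi, pi].
#' @param coupled_amp Amplitude series, same length, aligned samples.
#' @param binning A [phase_binning()].
#' @param alpha Significance level recorded alongside the p-value.
#' @param stat "median" (default) or "mean": the per-bin summary used to
#'   select the extreme bins.
#' @param sd_type Passed to [dprime()].
#' @param var_equal If TRUE use the pooled-variance t-test instead of
#'   Welch.
#' @param valid Optional logical mask; FALSE samples (e.g. edge-guarded)
#'   are excluded before binning.
#' @return Object of class `pac_result`: per-bin summaries and counts,
#'   extreme-bin indices and phase centers (`phi_max`, `phi_min`), the
#'   max/min bin moments (`mu1`, `sigma1`, `mu2`, `sigma2`), `dprime`,
#'   `p_value`, `n1`, `n2`, `significant`.
#' @export
pac_channel <- function(eeg_phase, coupled_amp, binning = phase_binning(),
                        alpha = 0.05, stat = c("median", "mean"),
                        sd_type = "sample", var_equal = FALSE,
                        valid = NULL) {
  stat <- match.arg(stat)
  if (length(eeg_phase) != length(coupled_amp))
    stop("pac_channel: phase and amplitude series must be equal length")
  if (!is.null(valid)) {
    eeg_phase <- eeg_phase[valid]
    coupled_amp <- coupled_amp[valid]
  }
  idx <- phase_bin_index(wrap_phase(eeg_phase), binning)
  counts <- tabulate(idx, nbins = binning$n_bins)
  if (any(counts == 0L))
    stop("pac_channel: empty phase bin(s): ",
         paste(which(counts == 0L), collapse = ", "),
         " (insufficient data)")
  groups <- split(coupled_amp, factor(idx, levels = seq_len(binning$n_bins)))
  summ <- if (stat == "median") vapply(groups, stats::median, 0)
          else vapply(groups, mean, 0)
  max_bin <- which.max(summ)
  min_bin <- which.min(summ)
  x1 <- groups[[max_bin]]
  x2 <- groups[[min_bin]]
  dp <- if (max_bin == min_bin) 0 else dprime(x1, x2, sd_type = sd_type)
  p <- if (max_bin == min_bin) 1 else {
    tt <- tryCatch(stats::t.test(x1, x2, var.equal = var_equal),
                   error = function(e) NULL)
    if (is.null(tt)) { warning("pac_channel: degenerate t-test; p = 1"); 1 }
    else tt$p.value
  }
  structure(
    list(bin_summary = unname(summ), bin_counts = counts, stat = stat,
         max_bin = unname(max_bin), min_bin = unname(min_bin),
         phi_max = binning$centers[max_bin],
         phi_min = binning$centers[min_bin],
         mu1 = mean(x1), sigma1 = stats::sd(x1),
         mu2 = mean(x2), sigma2 = stats::sd(x2),
         dprime = dp, p_value = p, n1 = length(x1), n2 = length(x2),
         alpha = alpha, significant = p < alpha),
    class = "pac_result")
}

#' @export
print.pac_result <- function(x, ...) {
  cat(sprintf("<pac_result> phi_max %.2f rad (bin %d), phi_min %.2f rad (bin %d)\n",
              x$phi_max, x$max_bin, x$phi_min, x$min_bin))
  cat(sprintf("  d-prime %.3f, p %.3g (n1 = %d, n2 = %d)\n",
              x$dprime, x$p_value, x$n1, x$n2))
  invisible(x)
}

#' Channel-wise phase-amplitude coupling for a preprocessed recording
#'
#' Runs [pac_channel()] for every EEG channel against the amplitude of one
#' peripheral channel. The peripheral "amplitude" is the highpass-filtered
#' signal value by default (`amp_type = "filtered"`); the Hilbert envelope
#' variant is available with `amp_type = "envelope"`.
#'
#' @param pp An `isa_preprocessed` object.
#' @param target Modality of the coupled channel: "GSR" or "RESP".
#' @param amp_type "filtered" or "envelope".
#' @param exclude_edges Drop edge-guarded samples (default TRUE).
#' @param ... Passed to [pac_channel()].
#' @return Data frame, one row per EEG channel: `channel`, `phi_max`,
#'   `phi_min`, `dprime`, `p_value`, `n1`, `n2`, `significant`.
#' @export
pac_subject <- function(pp, target = "GSR",
                        amp_type = c("filtered", "envelope"),
                        exclude_edges = TRUE, ...) {
  stopifnot(inherits(pp, "isa_preprocessed"))
  amp_type <- match.arg(amp_type)
  tch <- channels_of(pp, target)
  if (length(tch) == 0L) stop("pac_subject: no ", target, " channel")
  tch <- tch[1L]
  amp <- if (amp_type == "filtered") pp$filtered[tch, ] else pp$amplitude[tch, ]
  eeg <- channels_of(pp, "EEG")
  valid <- if (exclude_edges) pp$valid else NULL
  rows <- lapply(eeg, function(ch) {
    r <- pac_channel(pp$phase[ch, ], amp, valid = valid, ...)
    data.frame(channel = pp$channel_labels[ch], phi_max = r$phi_max,
               phi_min = r$phi_min, dprime = r$dprime,
               p_value = r$p_value, n1 = r$n1, n2 = r$n2,
               significant = r$significant)
  })
  out <- do.call(rbind, rows)
  attr(out, "subject_id") <- pp$subject_id
  attr(out, "target") <- target
  out
}

#' Per-subject summary of channel-wise coupling results
#'
#' @param results A data frame from [pac_subject()] (or a list of
#'   `pac_result` objects).
#' @param alpha Per-channel significance level (no multiple-comparison
#'   correction, matching the per-channel reporting convention; apply
#'   [stats::p.adjust()] to the p-values first for a corrected variant).
#' @return List of class `subject_pac_summary`: `sig_channel_ratio`,
#'   `mean_dprime`, `mean_phi_max` (circular mean), `icpc_phi_max`
#'   (resultant length of the per-channel preferred phases),
#'   `icpc_phi_min`, and `phase_diff` (per-channel wrapped
#'   phi_max - phi_min).
#' @export
subject_summary <- function(results, alpha = 0.05) {
  if (!is.data.frame(results)) {
    results <- do.call(rbind, lapply(results, function(r)
      data.frame(phi_max = r$phi_max, phi_min = r$phi_min,
                 dprime = r$dprime, p_value = r$p_value)))
  }
  if (nrow(results) == 0L) stop("subject_summary: no channels")
  structure(
    list(sig_channel_ratio = mean(results$p_value < alpha),
         mean_dprime = mean(results$dprime),
         mean_phi_max = circ_mean(results$phi_max),
         icpc_phi_max = resultant_length(results$phi_max),
         icpc_phi_min = resultant_length(results$phi_min),
         phase_diff = circ_diff(results$phi_max, results$phi_min),
         n_channels = nrow(results), alpha = alpha),
    class = "subject_pac_summary")
}

#' @export
print.subject_pac_summary <- function(x, ...) {
  cat(sprintf("<subject_pac_summary> %d channels: %.1f%% significant (alpha %.2g)\n",
              x$n_channels, 100 * x$sig_channel_ratio, x$alpha))
  cat(sprintf("  mean d-prime %.3f, mean phi_max %.2f rad, ICPC(phi_max) %.3f\n",
              x$mean_dprime, x$mean_phi_max, x$icpc_phi_max))
  invisible(x)
}
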