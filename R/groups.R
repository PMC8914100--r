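# Epoch extraction and group-level testing: trials are the first
# `epoch_len` seconds after each onset; subjects are split at the median
# of their channel-average d-prime; per-time-point two-sample t-tests
# compare groups, pooling subject x channel values as samples.

#' Extract per-trial epochs from a series
#'
#' One row per onset, covering `[onset, onset + epoch_len]` inclusive, so
#' the time axis has `epoch_len * fs + 1` points (0..epoch_len at 1 Hz).
#' Onsets whose epoch extends past the series end (or starts before it)
#' are dropped with a warning.
#'
#' @param x Numeric series at rate `fs` (values, phases, frequencies...).
#' @param onsets Onset times in seconds from series start.
#' @param epoch_len Epoch length in seconds.
#' @param fs Sampling rate in Hz.
#' @return Matrix of class `epoch_set`, trials x time, with attribute `t`
#'   (seconds from onset) and `onsets` (surviving onsets).
#' @export
extract_epochs <- function(x, onsets, epoch_len = 30, fs = 1) {
  n <- length(x)
  len <- as.integer(round(epoch_len * fs)) + 1L
  start <- round(onsets * fs) + 1L
  ok <- start >= 1L & (start + len - 1L) <= n
  if (!all(ok))
    warning("extract_epochs: dropping ", sum(!ok),
            " trial(s) not fully inside the recording")
  if (!any(ok)) stop("extract_epochs: no surviving trials")
  rows <- t(vapply(start[ok], function(s) x[s:(s + len - 1L)],
                   numeric(len)))
  structure(rows, t = (seq_len(len) - 1L) / fs, onsets = onsets[ok],
            class = c("epoch_set", "matrix"))
}

#' Median split of subjects by a scalar criterion
#'
#' Subjects are ranked by value (descending), ties broken by subject id
#' (ascending), and the top `floor(n/2)` form the high group -- with 24
#' subjects this yields the conventional 12/12 split. A fully tied input
#' has no meaningful order: it is an error unless `tie_break_seed` is
#' given, in which case the order is drawn at random (reproducibly).
#'
#' @param values Named numeric vector, one value per subject (e.g.
#'   channel-average d-prime).
#' @param tie_break_seed Optional seed to resolve a fully tied input.
#' @return List of class `group_split`: `high`, `low` (subject id
#'   character vectors), `criterion`, `threshold` (the boundary value).
#' @export
median_split <- function(values, tie_break_seed = NULL) {
  n <- length(values)
  if (n < 2L) stop("median_split: need at least 2 subjects")
  ids <- names(values)
  if (is.null(ids)) ids <- as.character(seq_len(n))
  if (length(unique(values)) == 1L) {
    if (is.null(tie_break_seed))
      stop("median_split: split undefined under ties (all values equal); ",
           "provide tie_break_seed")
    ord <- with_seed(tie_break_seed, sample.int(n))
  } else {
    ord <- order(-values, ids)
  }
  n_high <- n %/% 2L
  structure(list(high = ids[ord[seq_len(n_high)]],
                 low = ids[ord[(n_high + 1L):n]],
                 criterion = "median split",
                 threshold = unname(values[ord[n_high]])),
            class = "group_split")
}

#' @export
print.group_split <- function(x, ...) {
  cat(sprintf("<group_split> high (n = %d): %s\n", length(x$high),
              paste(x$high, collapse = ", ")))
  cat(sprintf("  low (n = %d): %s\n", length(x$low),
              paste(x$low, collapse = ", ")))
  invisible(x)
}

sem <- function(v) stats::sd(v) / sqrt(length(v))

safe_t_p <- function(a, b, alternative, var_equal) {
  tt <- tryCatch(stats::t.test(a, b, alternative = alternative,
                               var.equal = var_equal),
                 error = function(e) NULL)
  if (is.null(tt)) NA_real_ else tt$p.value
}

#' Per-time-point two-sample group test
#'
#' At each epoch time point, compares the pooled samples of group A
#' against group B with a t-test (Welch, two-sided by default). Rows of
#' `a` and `b` are the samples -- conventionally one per subject x channel
#' pair, so with full data the per-time-point sample size is
#' n_subjects x n_channels per group. Degenerate inputs (zero variance in
#' both groups) give p = 1 with a warning.
#'
#' @param a,b Numeric matrices, samples x time, equal number of columns.
#' @param alpha Significance level for the `significant` mask.
#' @param alternative Passed to [stats::t.test()].
#' @param var_equal Pooled-variance t-test if TRUE.
#' @param t Optional time axis (defaults to the `t` attribute of `a`, or
#'   0-based indices).
#' @return Data frame: `t`, `mean_a`, `mean_b`, `sem_a`, `sem_b`, `p`,
#'   `significant`.
#' @export
timepoint_group_test <- function(a, b, alpha = 0.05,
                                 alternative = "two.sided",
                                 var_equal = FALSE, t = NULL) {
  if (is.null(t)) t <- attr(a, "t")
  a <- unclass(as.matrix(a)); b <- unclass(as.matrix(b))
  if (ncol(a) != ncol(b))
    stop("timepoint_group_test: time axes differ")
  if (nrow(a) == 0L || nrow(b) == 0L)
    stop("timepoint_group_test: empty group")
  if (is.null(t)) t <- seq_len(ncol(a)) - 1
  p <- vapply(seq_len(ncol(a)), function(j)
    safe_t_p(a[, j], b[, j], alternative, var_equal), 0)
  if (anyNA(p)) {
    warning("timepoint_group_test: degenerate variance at ",
            sum(is.na(p)), " time point(s); p set to 1")
    p[is.na(p)] <- 1
  }
  data.frame(t = t,
             mean_a = colMeans(a), mean_b = colMeans(b),
             sem_a = apply(a, 2L, sem), sem_b = apply(b, 2L, sem),
             p = p, significant = p < alpha)
}

#' Test for decreases relative to an early-epoch baseline
#'
#' For each time point beyond the baseline window, a one-sided t-test asks
#' whether the samples at that time are lower than the per-sample means
#' over the first `baseline_window` seconds (unpaired by default; set
#' `paired = TRUE` to pair each sample with its own baseline). Intended
#' for instantaneous-frequency epochs where the samples are per
#' subject x channel medians.
#'
#' @param epochs Numeric matrix, samples x time (with `t` attribute in
#'   seconds, as produced via [extract_epochs()]).
#' @param baseline_window Baseline length in seconds: time points with
#'   `t < baseline_window` form the baseline.
#' @param alpha Significance level.
#' @param paired Pair samples with their own baseline means.
#' @return Data frame over the post-baseline time points: `t`, `mean`,
#'   `baseline_mean`, `p`, `significant`.
#' @export
baseline_decrease_test <- function(epochs, baseline_window = 10,
                                   alpha = 0.05, paired = FALSE) {
  tax <- attr(epochs, "t")
  epochs <- unclass(as.matrix(epochs))
  if (is.null(tax)) tax <- seq_len(ncol(epochs)) - 1
  base_cols <- which(tax < baseline_window)
  test_cols <- which(tax >= baseline_window)
  if (!length(base_cols) || !length(test_cols))
    stop("baseline_decrease_test: epoch does not cover baseline plus test points")
  baseline <- rowMeans(epochs[, base_cols, drop = FALSE])
  p <- vapply(test_cols, function(j) {
    pv <- if (paired)
      tryCatch(stats::t.test(epochs[, j], baseline, alternative = "less",
                             paired = TRUE)$p.value,
               error = function(e) NA_real_)
    else safe_t_p(epochs[, j], baseline, "less", FALSE)
    pv
  }, 0)
  if (anyNA(p)) {
    warning("baseline_decrease_test: degenerate variance; p set to 1")
    p[is.na(p)] <- 1
  }
  data.frame(t = tax[test_cols],
             mean = colMeans(epochs[, test_cols, drop = FALSE]),
             baseline_mean = mean(baseline),
             p = p, significant = p < alpha)
}
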