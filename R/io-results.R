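# Plain-text result writers: long-format TSV tables plus JSON sidecars
# recording every parameter needed to reproduce a run.

write_tsv <- function(df, path)
  utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)

#' Write a preprocessed recording to TSV plus a JSON parameter sidecar
#'
#' Long format: one row per (time, channel) with phase, amplitude,
#' filtered value and (EEG only) instantaneous frequency; edge-guarded
#' samples carry `valid = FALSE`. The sidecar holds every preprocessing
#' parameter.
#'
#' @param pp An `isa_preprocessed`.
#' @param path Output TSV path; the sidecar is `<path>.json`.
#' @return Invisibly, the two paths.
#' @export
write_preprocessed <- function(pp, path) {
  stopifnot(inherits(pp, "isa_preprocessed"))
  n <- ncol(pp$phase)
  tt <- (seq_len(n) - 1L) / pp$fs
  df <- do.call(rbind, lapply(seq_len(nrow(pp$phase)), function(ch)
    data.frame(time = tt, channel = pp$channel_labels[ch],
               modality = pp$modality[ch],
               phase = pp$phase[ch, ], amplitude = pp$amplitude[ch, ],
               filtered = pp$filtered[ch, ], ifreq = pp$ifreq[ch, ],
               valid = pp$valid)))
  write_tsv(df, path)
  side <- paste0(path, ".json")
  jsonlite::write_json(
    c(pp$params, list(subject_id = pp$subject_id, fs = pp$fs,
                      n_samples = n, channel_labels = pp$channel_labels,
                      modality = pp$modality,
                      trial_onsets = pp$trial_onsets)),
    side, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(list(tsv = path, sidecar = side))
}

#' Write channel-wise coupling results and the subject summary
#'
#' @param results Data frame from [pac_subject()].
#' @param path Output TSV path; the JSON subject summary is
#'   `<path>.json`.
#' @param alpha Significance level for the summary.
#' @return Invisibly, the two paths.
#' @export
write_pac_results <- function(results, path, alpha = 0.05) {
  df <- cbind(subject = attr(results, "subject_id"), results)
  write_tsv(df, path)
  s <- subject_summary(results, alpha = alpha)
  side <- paste0(path, ".json")
  jsonlite::write_json(
    list(subject = attr(results, "subject_id"),
         target = attr(results, "target"),
         sig_channel_ratio = s$sig_channel_ratio,
         mean_dprime = s$mean_dprime, mean_phi_max = s$mean_phi_max,
         icpc_phi_max = s$icpc_phi_max, n_channels = s$n_channels,
         alpha = alpha),
    side, auto_unbox = TRUE, digits = NA)
  invisible(list(tsv = path, sidecar = side))
}

#' Write an ITPC time course (long format) with run metadata
#'
#' @param series An [itpc_timecourse()] result.
#' @param path Output TSV path.
#' @param null Optional [itpc_null()]; when given, per-time p-values and
#'   the null 95% level are included.
#' @param subject,channel Identifier columns.
#' @return Invisibly, the two paths.
#' @export
write_itpc_results <- function(series, path, null = NULL,
                               subject = "", channel = "") {
  df <- data.frame(subject = subject, channel = channel,
                   t = series$t, itpc = series$itpc)
  meta <- list(n_trials = series$n_trials)
  if (!is.null(null)) {
    df$p <- itpc_pvalue(null, series$itpc)
    meta <- c(meta, list(n_perm = null$n_perm, seed = null$seed,
                         null95 = itpc_null_quantile(null)))
  }
  write_tsv(df, path)
  side <- paste0(path, ".json")
  jsonlite::write_json(meta, side, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(list(tsv = path, sidecar = side))
}

#' Write a lag-scan result (long format) with run metadata
#'
#' @param scan A [lag_scan()] result.
#' @param path Output TSV path.
#' @param subject,channel Identifier columns.
#' @return Invisibly, the two paths.
#' @export
write_lagscan_results <- function(scan, path, subject = "", channel = "") {
  write_tsv(data.frame(subject = subject, channel = channel,
                       lag = scan$lags, icpc = scan$icpc_by_lag), path)
  side <- paste0(path, ".json")
  jsonlite::write_json(
    list(best_lag = scan$best_lag, best_icpc = scan$best_icpc,
         null95 = scan$null95, n_null = scan$n_null),
    side, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(list(tsv = path, sidecar = side))
}
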