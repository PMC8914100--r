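#' Multichannel physiological recording
#'
#' Container for a synchronously sampled multichannel recording (EEG plus
#' peripheral channels) with trial-onset events. All channels share one
#' sampling rate and length. Construction validates the invariants the
#' downstream statistics rely on; in particular any non-finite sample is a
#' hard error (silent interpolation would bias the phase statistics).
#'
#' @param data Numeric matrix, channels x samples.
#' @param fs Sampling rate in Hz (> 0).
#' @param channel_labels Character vector, one label per channel.
#' @param modality Character vector per channel; each of "EEG", "GSR" or
#'   "RESP".
#' @param trial_onsets Trial onset times in seconds from recording start;
#'   strictly increasing, within the recording.
#' @param subject_id Subject identifier.
#' @param group_label Optional group label (e.g. "expert"/"novice").
#' @return An object of class `isa_recording`.
#' @export
recording <- function(data, fs, channel_labels, modality,
                      trial_onsets = numeric(0),
                      subject_id = "", group_label = NULL) {
  if (!is.matrix(data) || !is.numeric(data))
    stop("data must be a numeric channels x samples matrix")
  if (!is.numeric(fs) || length(fs) != 1L || fs <= 0)
    stop("fs must be a single positive number")
  nc <- nrow(data)
  if (length(channel_labels) != nc)
    stop("channel_labels length (", length(channel_labels),
         ") != number of channels (", nc, ")")
  if (length(modality) != nc)
    stop("modality length (", length(modality),
         ") != number of channels (", nc, ")")
  bad_mod <- setdiff(unique(modality), c("EEG", "GSR", "RESP"))
  if (length(bad_mod))
    stop("unknown modality: ", paste(bad_mod, collapse = ", "))
  fin <- is.finite(data)
  if (!all(fin)) {
    ch <- which(!apply(fin, 1L, all))[1L]
    stop("non-finite samples in channel '", channel_labels[ch], "'")
  }
  duration <- ncol(data) / fs
  trial_onsets <- as.numeric(trial_onsets)
  if (length(trial_onsets)) {
    if (any(diff(trial_onsets) <= 0))
      stop("trial_onsets must be strictly increasing")
    if (min(trial_onsets) < 0 || max(trial_onsets) > duration)
      stop("trial_onsets must lie within [0, ", duration, "] s")
  }
  structure(
    list(data = data, fs = fs,
         channel_labels = as.character(channel_labels),
         modality = as.character(modality),
         trial_onsets = trial_onsets,
         subject_id = as.character(subject_id),
         group_label = group_label),
    class = "isa_recording")
}

#' @export
print.isa_recording <- function(x, ...) {
  cat(sprintf("<isa_recording> subject '%s'%s\n", x$subject_id,
              if (is.null(x$group_label)) "" else
                sprintf(" [%s]", x$group_label)))
  cat(sprintf("  %d channels (%d EEG, %d GSR, %d RESP), %.0f samples @ %g Hz (%.1f s)\n",
              nrow(x$data), sum(x$modality == "EEG"),
              sum(x$modality == "GSR"), sum(x$modality == "RESP"),
              ncol(x$data), x$fs, ncol(x$data) / x$fs))
  cat(sprintf("  %d trial onsets\n", length(x$trial_onsets)))
  invisible(x)
}

#' Duration of a recording in seconds
#' @param rec An `isa_recording`.
#' @return Seconds.
#' @export
recording_duration <- function(rec) ncol(rec$data) / rec$fs

#' Indices of channels of a given modality
#' @param x An `isa_recording` or `isa_preprocessed` object.
#' @param modality One of "EEG", "GSR", "RESP".
#' @return Integer channel indices.
#' @export
channels_of <- function(x, modality) which(x$modality == modality)
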