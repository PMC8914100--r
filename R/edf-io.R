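# EDF (16-bit) and BioSemi BDF (24-bit) reading/writing. Both formats share
# the same fixed-width ASCII header layout: 256 bytes of global fields plus
# 256 bytes per signal, followed by data records of little-endian integers
# scaled linearly between the declared digital and physical ranges.
#
# Restrictions (sufficient for this package's sessions): every signal has
# the same sampling rate, record duration is 1 s, and the sampling rate is
# an integer.

pad_field <- function(s, width) {
  s <- as.character(s)[1L]
  if (nchar(s) > width) s <- substr(s, 1L, width)
  formatC(s, width = -width, flag = " ")
}

# format a number into <= `width` ASCII chars that parse back exactly
fmt_num8 <- function(x, width = 8) {
  for (d in 8:1) {
    s <- formatC(x, format = "g", digits = d, width = -1)
    if (nchar(s) <= width && !is.na(as.numeric(s))) return(s)
  }
  stop("cannot format ", x, " into ", width, " characters")
}

#' Write a recording to an EDF or BDF file
#'
#' Writes the sample data with per-channel linear scaling chosen from the
#' data range (symmetric, slightly padded, so the quantization step is about
#' range / 2^16 for EDF and range / 2^24 for BDF). Trial onsets are not part
#' of the EDF payload; use [write_session()] to emit the companion events
#' table as well.
#'
#' @param rec An [recording()] object with integer sampling rate.
#' @param path Output file path.
#' @param format "edf" (16-bit) or "bdf" (24-bit BioSemi).
#' @return `path`, invisibly.
#' @export
write_edf <- function(rec, path, format = c("edf", "bdf")) {
  format <- match.arg(format)
  fs <- rec$fs
  if (abs(fs - round(fs)) > 1e-9)
    stop("write_edf: sampling rate must be an integer (got ", fs, ")")
  fs <- as.integer(round(fs))
  nch <- nrow(rec$data)
  nsamp <- ncol(rec$data)
  spr <- fs                               # 1-s records
  nrec <- nsamp %/% spr
  if (nrec < 1L) stop("write_edf: recording shorter than one data record")
  if (nrec * spr != nsamp) {
    warning("write_edf: truncating ", nsamp - nrec * spr,
            " trailing samples to complete 1-s records")
    nsamp <- nrec * spr
  }
  dig_max <- if (format == "edf") 32767L else 8388607L
  dig_min <- if (format == "edf") -32768L else -8388608L

  # physical range is symmetric +/- pm; format pm to 7 chars so that both
  # "pm" and "-pm" fit the 8-char header fields with identical precision
  pmax_str <- character(nch)
  dig <- matrix(0L, nch, nsamp)
  for (ch in seq_len(nch)) {
    x <- rec$data[ch, seq_len(nsamp)]
    m <- max(abs(x), 1e-6)
    ps <- fmt_num8(m * 1.05, width = 7)
    while (as.numeric(ps) < m) ps <- fmt_num8(as.numeric(ps) * 1.1, width = 7)
    pmax_str[ch] <- ps
    pm <- as.numeric(ps)
    d <- round((x + pm) / (2 * pm) * (dig_max - dig_min)) + dig_min
    dig[ch, ] <- as.integer(pmin(pmax(d, dig_min), dig_max))
  }

  con <- file(path, "wb")
  on.exit(close(con))
  if (format == "bdf") {
    writeBin(as.raw(255L), con)
    writeChar("BIOSEMI", con, nchars = 7L, eos = NULL)
  } else {
    writeChar(pad_field("0", 8L), con, eos = NULL)
  }
  writeChar(pad_field(rec$subject_id, 80L), con, eos = NULL)
  writeChar(pad_field("Startdate 01-JAN-2000", 80L), con, eos = NULL)
  writeChar(pad_field("01.01.00", 8L), con, eos = NULL)
  writeChar(pad_field("00.00.00", 8L), con, eos = NULL)
  writeChar(pad_field(256L * (nch + 1L), 8L), con, eos = NULL)
  writeChar(pad_field(if (format == "bdf") "24BIT" else "", 44L),
            con, eos = NULL)
  writeChar(pad_field(nrec, 8L), con, eos = NULL)
  writeChar(pad_field("1", 8L), con, eos = NULL)
  writeChar(pad_field(nch, 4L), con, eos = NULL)

  wr <- function(vals, width)
    for (v in vals) writeChar(pad_field(v, width), con, eos = NULL)
  phys_dim <- ifelse(rec$modality == "EEG", "uV",
                     ifelse(rec$modality == "GSR", "uS", "au"))
  wr(rec$channel_labels, 16L)
  wr(rep("", nch), 80L)
  wr(phys_dim, 8L)
  wr(paste0("-", pmax_str), 8L)
  wr(pmax_str, 8L)
  wr(rep(dig_min, nch), 8L)
  wr(rep(dig_max, nch), 8L)
  wr(rep("", nch), 80L)
  wr(rep(spr, nch), 8L)
  wr(rep("", nch), 32L)

  # record-major, signal-major-within-record layout
  arr <- array(dig, dim = c(nch, spr, nrec))
  flat <- as.vector(aperm(arr, c(2L, 1L, 3L)))
  if (format == "edf") {
    writeBin(flat, con, size = 2L, endian = "little")
  } else {
    u <- flat
    u[u < 0L] <- u[u < 0L] + 16777216
    bytes <- rbind(u %% 256, (u %/% 256) %% 256, u %/% 65536)
    writeBin(as.raw(as.vector(bytes)), con)
  }
  invisible(path)
}

read_header_field <- function(raw, offset, width) {
  trimws(rawToChar(raw[(offset + 1L):(offset + width)]))
}

#' Read an EDF or BDF file
#'
#' The format is detected from the leading magic byte (0xFF = BDF). Returns
#' the physically scaled samples; all signals must share one sampling rate.
#'
#' @param path File path.
#' @return List with `data` (channels x samples matrix), `fs`,
#'   `channel_labels`, `phys_dim` and `format`.
#' @export
read_edf <- function(path) {
  if (!file.exists(path)) stop("read_edf: no such file: ", path)
  sz <- file.info(path)$size
  con <- file(path, "rb")
  on.exit(close(con))
  hdr0 <- readBin(con, "raw", 256L)
  if (length(hdr0) < 256L) stop("read_edf: not an EDF/BDF file (truncated header)")
  is_bdf <- hdr0[1L] == as.raw(255L)
  if (is_bdf && read_header_field(hdr0, 1L, 7L) != "BIOSEMI")
    stop("read_edf: unrecognized format (0xFF magic but not BIOSEMI)")
  subject <- read_header_field(hdr0, 8L, 80L)
  nrec <- as.integer(read_header_field(hdr0, 236L, 8L))
  rec_dur <- as.numeric(read_header_field(hdr0, 244L, 8L))
  nch <- as.integer(read_header_field(hdr0, 252L, 4L))
  if (is.na(nch) || nch < 1L) stop("read_edf: malformed header (signal count)")

  hdr1 <- readBin(con, "raw", 256L * nch)
  fld <- function(off0, width)
    vapply(seq_len(nch) - 1L, function(i)
      read_header_field(hdr1, off0 * nch + i * width, width), "")
  labels <- fld(0L, 16L)
  phys_dim <- fld(96L, 8L)
  pmin <- as.numeric(fld(104L, 8L))
  pmax <- as.numeric(fld(112L, 8L))
  dmin <- as.numeric(fld(120L, 8L))
  dmax <- as.numeric(fld(128L, 8L))
  spr <- as.integer(fld(216L, 8L))
  if (length(unique(spr)) != 1L)
    stop("read_edf: signals with differing sampling rates are not supported")
  spr <- spr[1L]
  fs <- spr / rec_dur
  bps <- if (is_bdf) 3L else 2L
  if (nrec < 0L)  # unknown record count: infer from file size
    nrec <- as.integer((sz - 256L * (nch + 1L)) %/% (bps * spr * nch))

  ntot <- nrec * nch * spr
  if (is_bdf) {
    b <- as.integer(readBin(con, "raw", 3L * ntot))
    if (length(b) < 3L * ntot) stop("read_edf: truncated data section")
    u <- b[c(TRUE, FALSE, FALSE)] + 256 * b[c(FALSE, TRUE, FALSE)] +
      65536 * b[c(FALSE, FALSE, TRUE)]
    flat <- ifelse(u >= 8388608, u - 16777216, u)
  } else {
    flat <- readBin(con, "integer", ntot, size = 2L, signed = TRUE,
                    endian = "little")
    if (length(flat) < ntot) stop("read_edf: truncated data section")
  }
  arr <- array(flat, dim = c(spr, nch, nrec))
  dig <- matrix(aperm(arr, c(2L, 1L, 3L)), nrow = nch)
  scale <- (pmax - pmin) / (dmax - dmin)
  data <- (dig - dmin) * scale + pmin
  list(data = data, fs = fs, channel_labels = labels, phys_dim = phys_dim,
       subject_id = subject, format = if (is_bdf) "bdf" else "edf")
}

#' Default channel-label to modality mapping
#'
#' Case-insensitive regular expressions tried in order; the first match
#' assigns the modality. The trailing EEG pattern matches anything, so by
#' default no channel is left unclassified.
#'
#' @return Named character vector of regexes.
#' @export
default_modality_patterns <- function()
  c(GSR = "GSR|EDA|SKIN|CONDUCT", RESP = "RESP|BREATH|PNEU", EEG = ".")

match_modality <- function(labels, patterns) {
  out <- rep(NA_character_, length(labels))
  for (mod in names(patterns)) {
    hit <- grepl(patterns[[mod]], labels, ignore.case = TRUE) & is.na(out)
    out[hit] <- mod
  }
  if (anyNA(out))
    stop("no modality pattern matches channel(s): ",
         paste(labels[is.na(out)], collapse = ", "))
  out
}

#' Read a BIDS-style events table
#'
#' @param path TSV file with at least an `onset` column (seconds).
#' @return Data frame with `onset` and (if present) `duration` columns.
#' @export
read_events_tsv <- function(path) {
  ev <- utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE)
  if (!"onset" %in% names(ev))
    stop("events table ", path, " has no 'onset' column")
  ev
}

#' Read a recording from an EDF/BDF file plus companion events table
#'
#' Channels are tagged with a modality by matching their labels against
#' `modality_patterns`. When `events_path` is `NULL` the sibling file
#' `<stem>_events.tsv` is used; a missing events table yields a recording
#' with empty `trial_onsets` and a warning.
#'
#' @param path EDF or BDF file.
#' @param events_path Optional events TSV path.
#' @param modality_patterns See [default_modality_patterns()].
#' @param subject_id Overrides the subject field stored in the file.
#' @param group_label Optional group label.
#' @return An [recording()] object.
#' @export
read_recording <- function(path, events_path = NULL,
                           modality_patterns = default_modality_patterns(),
                           subject_id = NULL, group_label = NULL) {
  raw <- read_edf(path)
  modality <- match_modality(raw$channel_labels, modality_patterns)
  if (is.null(events_path))
    events_path <- sub("\\.(edf|bdf)$", "_events.tsv", path,
                       ignore.case = TRUE)
  onsets <- numeric(0)
  if (file.exists(events_path)) {
    onsets <- as.numeric(read_events_tsv(events_path)$onset)
  } else {
    warning("no events table found at ", events_path,
            "; recording has no trial onsets")
  }
  recording(raw$data, raw$fs, raw$channel_labels, modality,
            trial_onsets = onsets,
            subject_id = if (is.null(subject_id)) raw$subject_id else subject_id,
            group_label = group_label)
}

#' Write a recording as EDF/BDF plus a BIDS-style events table
#'
#' @param rec An [recording()] object.
#' @param dir Output directory (created if needed).
#' @param name File stem; defaults to the subject id (or "session").
#' @param format "edf" or "bdf".
#' @param trial_durations Optional durations (seconds) for the events table;
#'   defaults to 0.
#' @return Invisibly, a list with `recording` and `events` file paths.
#' @export
write_session <- function(rec, dir, name = NULL, format = c("edf", "bdf"),
                          trial_durations = NULL) {
  format <- match.arg(format)
  if (is.null(name))
    name <- if (nzchar(rec$subject_id)) rec$subject_id else "session"
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  rec_path <- file.path(dir, paste0(name, ".", format))
  ev_path <- file.path(dir, paste0(name, "_events.tsv"))
  write_edf(rec, rec_path, format = format)
  dur <- trial_durations
  if (is.null(dur)) dur <- rep(0, length(rec$trial_onsets))
  utils::write.table(
    data.frame(onset = rec$trial_onsets, duration = dur),
    ev_path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(list(recording = rec_path, events = ev_path))
}
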