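#' Read an EDF (European Data Format) recording
#'
#' Minimal reader for uncompressed EDF/EDF+ continuous recordings: parses
#' the ASCII header and the 16-bit little-endian sample records, applies
#' the per-channel digital-to-physical calibration, and returns the signal
#' matrix. Annotation channels ("EDF Annotations") are dropped.
#'
#' @param path `.edf` file.
#' @return List with `signals` (`C x T` matrix, physical units),
#'   `channel_names`, `fs` (per retained channel, Hz), `n_records`,
#'   `record_s`.
#' @export
read_edf <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  hdr <- function(n) trimws(rawToChar(readBin(con, "raw", n)))
  version <- hdr(8)
  patient <- hdr(80); recording <- hdr(80)
  startdate <- hdr(8); starttime <- hdr(8)
  header_bytes <- as.integer(hdr(8))
  reserved <- hdr(44)
  n_records <- as.integer(hdr(8))
  record_s <- as.numeric(hdr(8))
  ns <- as.integer(hdr(4))
  if (is.na(ns) || ns < 1) stop("not a valid EDF header: ", path)
  field <- function(w) vapply(seq_len(ns), function(i) hdr(w), character(1))
  labels <- field(16)
  transducer <- field(80)
  phys_dim <- field(8)
  phys_min <- as.numeric(field(8)); phys_max <- as.numeric(field(8))
  dig_min <- as.numeric(field(8)); dig_max <- as.numeric(field(8))
  prefilter <- field(80)
  nsamp <- as.integer(field(8))
  field(32)                                   # per-channel reserved
  keep <- labels != "EDF Annotations"
  gain <- (phys_max - phys_min) / (dig_max - dig_min)
  offset <- phys_min - gain * dig_min
  sig <- lapply(seq_len(ns), function(i)
    numeric(if (keep[i]) nsamp[i] * n_records else 0))
  for (r in seq_len(n_records)) {
    for (i in seq_len(ns)) {
      raw <- readBin(con, "integer", n = nsamp[i], size = 2,
                     endian = "little", signed = TRUE)
      if (keep[i])
        sig[[i]][(r - 1) * nsamp[i] + seq_len(nsamp[i])] <-
          gain[i] * raw + offset[i]
    }
  }
  sig <- sig[keep]
  lens <- lengths(sig)
  if (length(unique(lens)) != 1)
    stop("channels have differing sample counts; not a uniform recording")
  list(signals = do.call(rbind, sig),
       channel_names = labels[keep],
       fs = nsamp[keep] / record_s,
       n_records = n_records, record_s = record_s)
}

#' Write a minimal EDF file
#'
#' Companion writer used to build test fixtures and export continuous
#' recordings; one data record per `record_s` seconds, 16-bit samples
#' scaled to the per-channel physical range.
#'
#' @param signals `C x T` numeric matrix.
#' @param channel_names length-`C` labels.
#' @param fs sampling rate, Hz (shared by all channels).
#' @param path output path.
#' @param record_s record duration, seconds (default 1; `T` must divide
#'   into whole records).
#' @return `path`, invisibly.
#' @export
write_edf <- function(signals, channel_names, fs, path, record_s = 1) {
  C <- nrow(signals); Tn <- ncol(signals)
  nsamp <- round(fs * record_s)
  if (Tn %% nsamp != 0)
    stop("signal length must be a whole number of records")
  n_records <- Tn %/% nsamp
  phys_min <- apply(signals, 1, min); phys_max <- apply(signals, 1, max)
  same <- phys_max - phys_min < 1e-12
  phys_max[same] <- phys_min[same] + 1
  dig_min <- -32768; dig_max <- 32767
  pad <- function(x, w) formatC(as.character(x), width = w, flag = "-")
  con <- file(path, "wb")
  on.exit(close(con))
  wr <- function(x, w) writeBin(charToRaw(pad(x, w)), con)
  wr("0", 8); wr("X", 80); wr("bcitransfer synthetic", 80)
  wr("01.01.26", 8); wr("00.00.00", 8)
  wr(256 + 256 * C, 8); wr("", 44)
  wr(n_records, 8); wr(format(record_s), 8); wr(C, 4)
  for (nm in channel_names) wr(substr(nm, 1, 16), 16)
  for (i in seq_len(C)) wr("", 80)
  for (i in seq_len(C)) wr("uV", 8)
  for (v in phys_min) wr(format(v, digits = 6), 8)
  for (v in phys_max) wr(format(v, digits = 6), 8)
  for (i in seq_len(C)) wr(dig_min, 8)
  for (i in seq_len(C)) wr(dig_max, 8)
  for (i in seq_len(C)) wr("", 80)
  for (i in seq_len(C)) wr(nsamp, 8)
  for (i in seq_len(C)) wr("", 32)
  gain <- (phys_max - phys_min) / (dig_max - dig_min)
  for (r in seq_len(n_records)) {
    for (i in seq_len(C)) {
      x <- signals[i, (r - 1) * nsamp + seq_len(nsamp)]
      d <- round((x - phys_min[i]) / gain[i]) + dig_min
      writeBin(as.integer(pmin(dig_max, pmax(dig_min, d))), con,
               size = 2, endian = "little")
    }
  }
  invisible(path)
}

#' Import an EDF recording as epoched trials
#'
#' Cuts a continuous EDF recording into fixed-length trials given onsets
#' and labels, mapping channel names onto a montage.
#'
#' @param path `.edf` file.
#' @param onsets_s trial onsets in seconds.
#' @param labels integer class index per trial.
#' @param trial_s trial length, seconds.
#' @param montage optional list with `names`/`xyz`; defaults to
#'   [standard_montage()] matched by channel count.
#' @param subject_id identifier.
#' @return A [trial_set()].
#' @export
edf_to_trial_set <- function(path, onsets_s, labels, trial_s,
                             montage = NULL, subject_id = "s01") {
  rec <- read_edf(path)
  fs <- rec$fs[1]
  if (any(rec$fs != fs)) stop("channels have differing sampling rates")
  if (is.null(montage))
    montage <- standard_montage(nrow(rec$signals))
  L <- round(trial_s * fs)
  trials <- lapply(onsets_s, function(t0) {
    i0 <- round(t0 * fs) + 1
    if (i0 + L - 1 > ncol(rec$signals))
      stop("trial at ", t0, " s extends past the recording")
    rec$signals[, i0:(i0 + L - 1), drop = FALSE]
  })
  trial_set(trials, labels, fs, rec$channel_names, montage$xyz,
            subject_id, n_classes = max(labels))
}
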