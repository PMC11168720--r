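# Minimal 16-bit EDF reader/writer (base R binary I/O). Standard EDF only;
# EDF+ annotation signals are tolerated on read and skipped.

pad <- function(s, n) {
  s <- substr(as.character(s), 1L, n)
  formatC(s, width = -n, flag = " ")
}

#' Write a multichannel recording to EDF
#'
#' Writes standard 16-bit EDF with a 1-second record duration. Physical
#' scaling is per channel from the data range. Used by the synthetic-data
#' module so that the reader can be exercised end to end.
#'
#' @param path output file.
#' @param signals numeric matrix, channels x samples.
#' @param fs sampling rate in Hz (integer; one data record per second).
#' @param labels channel labels, e.g. `"EEG Fp1"`, `"ECG"`.
#' @param units physical dimension per channel (default `"uV"`).
#' @param start_time `"hh.mm.ss"` recording start clock time.
#' @return `path`, invisibly.
#' @export
write_edf <- function(path, signals, fs, labels,
                      units = rep("uV", nrow(signals)),
                      start_time = "00.00.00") {
  stopifnot(is.matrix(signals), nrow(signals) == length(labels),
            fs == as.integer(fs), fs > 0)
  ns <- nrow(signals)
  n_rec <- floor(ncol(signals) / fs)
  if (n_rec < 1L) stopf("less than one full 1-s data record")
  signals <- signals[, seq_len(n_rec * fs), drop = FALSE]
  pmin_ <- apply(signals, 1, min); pmax_ <- apply(signals, 1, max)
  flat <- pmax_ - pmin_ < .Machine$double.eps
  pmin_[flat] <- pmin_[flat] - 1; pmax_[flat] <- pmax_[flat] + 1
  dmin <- -32768L; dmax <- 32767L

  con <- file(path, "wb"); on.exit(close(con))
  hdr <- paste0(pad("0", 8), pad("synthetic subject", 80),
                pad("synthetic recording", 80),
                pad("01.01.24", 8), pad(start_time, 8),
                pad(256L * (1L + ns), 8), pad("", 44),
                pad(n_rec, 8), pad(1L, 8), pad(ns, 4))
  writeChar(hdr, con, eos = NULL)
  field <- function(vals, w) writeChar(paste(vapply(vals, pad, "", w),
                                             collapse = ""), con, eos = NULL)
  field(labels, 16); field(rep("", ns), 80); field(units, 8)
  field(formatC(pmin_, format = "g", digits = 7), 8)
  field(formatC(pmax_, format = "g", digits = 7), 8)
  field(rep(dmin, ns), 8); field(rep(dmax, ns), 8)
  field(rep("", ns), 80); field(rep(fs, ns), 8); field(rep("", ns), 32)

  scale <- (pmax_ - pmin_) / (dmax - dmin)
  dig <- round(sweep(sweep(signals, 1, pmin_), 1, scale, "/")) + dmin
  dig <- pmin(pmax(dig, dmin), dmax)
  for (r in seq_len(n_rec)) {
    cols <- ((r - 1L) * fs + 1L):(r * fs)
    writeBin(as.integer(t(dig[, cols, drop = FALSE])), con,
             size = 2L, endian = "little")
  }
  invisible(path)
}

#' Read an EDF file
#'
#' @param path EDF file.
#' @return list with `signals` (channels x samples matrix), `fs` (per-channel
#'   sampling rates), `labels`, `units`, `start_time`, `n_records`,
#'   `record_duration_s`.
#' @export
read_edf <- function(path) {
  if (!file.exists(path)) stopf("no such file: %s", path)
  con <- file(path, "rb"); on.exit(close(con))
  rd <- function(n) {
    raw <- readBin(con, "raw", n)
    trimws(rawToChar(raw))
  }
  version <- rd(8)
  if (!identical(version, "0")) stopf("not an EDF file (version field '%s')", version)
  invisible(rd(80)); invisible(rd(80)); invisible(rd(8))
  start_time <- rd(8)
  hdr_bytes <- as.integer(rd(8)); invisible(rd(44))
  n_rec <- as.integer(rd(8)); rec_dur <- as.numeric(rd(8))
  ns <- as.integer(rd(4))
  if (is.na(ns) || ns < 1L) stopf("malformed EDF header")
  fields <- function(w) vapply(seq_len(ns), function(i) rd(w), "")
  labels <- fields(16); invisible(fields(80)); units <- fields(8)
  pmin_ <- as.numeric(fields(8)); pmax_ <- as.numeric(fields(8))
  dmin <- as.numeric(fields(8)); dmax <- as.numeric(fields(8))
  invisible(fields(80)); spr <- as.integer(fields(8)); invisible(fields(32))
  seek(con, hdr_bytes)

  keep <- !grepl("EDF Annotations", labels, fixed = TRUE)
  total <- sum(spr)
  out <- lapply(spr, function(k) numeric(k * n_rec))
  raw <- readBin(con, "integer", n = total * n_rec, size = 2L,
                 endian = "little", signed = TRUE)
  if (length(raw) < total * n_rec) stopf("truncated EDF data section")
  offs <- c(0L, cumsum(spr))
  for (r in seq_len(n_rec)) {
    base <- (r - 1L) * total
    for (s in seq_len(ns)) {
      if (!keep[s]) next
      out[[s]][((r - 1L) * spr[s] + 1L):(r * spr[s])] <-
        raw[(base + offs[s] + 1L):(base + offs[s] + spr[s])]
    }
  }
  scale <- (pmax_ - pmin_) / (dmax - dmin)
  sig <- lapply(which(keep), function(s) (out[[s]] - dmin[s]) * scale[s] + pmin_[s])
  list(signals = do.call(rbind, sig), fs = spr[keep] / rec_dur,
       labels = labels[keep], units = units[keep], start_time = start_time,
       n_records = n_rec, record_duration_s = rec_dur)
}

#' Parse a seizure annotation file
#'
#' One onset/offset pair per line, whitespace- or comma-separated, either in
#' seconds from record start or as clock times `HH:MM:SS[.sss]` (converted to
#' seconds relative to `start_time`, wrapping past midnight). Lines starting
#' with `#` are ignored.
#'
#' @param path annotation text file.
#' @param start_time recording start `"hh.mm.ss"` (needed for clock-time
#'   annotations).
#' @return data.frame with `onset_s`, `offset_s`.
#' @export
read_annotations <- function(path, start_time = "00.00.00") {
  if (!file.exists(path)) stopf("no such file: %s", path)
  lines <- trimws(readLines(path, warn = FALSE))
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  t0 <- clock_to_s(gsub("\\.", ":", start_time))
  parse_one <- function(tok) {
    if (grepl(":", tok)) {
      s <- clock_to_s(tok) - t0
      if (s < 0) s <- s + 86400
      s
    } else as.numeric(tok)
  }
  out <- do.call(rbind, lapply(lines, function(l) {
    tok <- strsplit(l, "[,;[:space:]]+")[[1]]
    if (length(tok) < 2L) stopf("malformed annotation line: '%s'", l)
    c(parse_one(tok[1]), parse_one(tok[2]))
  }))
  df <- data.frame(onset_s = out[, 1], offset_s = out[, 2])
  if (any(df$offset_s <= df$onset_s)) stopf("annotation with offset <= onset")
  df
}

clock_to_s <- function(x) {
  p <- as.numeric(strsplit(x, ":")[[1]])
  if (length(p) != 3L || anyNA(p)) stopf("bad clock time '%s'", x)
  p[1] * 3600 + p[2] * 60 + p[3]
}

#' Read a recording plus its seizure annotations
#'
#' Reads an EDF file, identifies the ECG channel (label containing
#' `"ECG"`/`"EKG"`), maps the remaining channels onto the reference
#' 29-channel 10-20 montage (labels such as `"EEG Fp1"` are stripped of
#' their prefix), and attaches montage coordinates. Reference channels
#' absent from the file are reported with a warning and the recording
#' proceeds on the available set (as for subjects recorded with a reduced
#' montage).
#'
#' @param path EDF file.
#' @param annotation_path text annotation file (see [read_annotations()]);
#'   `NULL` for none.
#' @return list with `recording` (a `physio_recording`) and `annotations`
#'   (data.frame of onset/offset seconds).
#' @export
read_recording <- function(path, annotation_path = NULL) {
  edf <- read_edf(path)
  lab <- trimws(sub("^EEG[ _]*", "", edf$labels, ignore.case = TRUE))
  is_ecg <- grepl("ECG|EKG", edf$labels, ignore.case = TRUE)
  if (!any(is_ecg)) stopf("no ECG derivation found in %s", path)
  ref <- montage_labels()
  hit <- match(tolower(ref), tolower(lab))
  present <- !is.na(hit)
  if (!any(present)) stopf("no reference EEG channels found in %s", path)
  missing_lab <- ref[!present]
  if (length(missing_lab))
    warnf("channels absent from recording: %s", paste(missing_lab, collapse = ", "))
  sel <- hit[present]
  fs <- unique(edf$fs[c(sel, which(is_ecg)[1])])
  if (length(fs) != 1L) stopf("EEG and ECG sampling rates differ")
  rec <- physio_recording(eeg = edf$signals[sel, , drop = FALSE],
                          ecg = edf$signals[which(is_ecg)[1], ],
                          fs = fs, channel_labels = ref[present],
                          subject_id = basename(path))
  ann <- if (is.null(annotation_path)) {
    data.frame(onset_s = numeric(0), offset_s = numeric(0))
  } else read_annotations(annotation_path, edf$start_time)
  dur <- ncol(rec$eeg) / fs
  if (nrow(ann) && any(ann$onset_s < 0 | ann$offset_s > dur + 1e-9))
    stopf("annotation outside record duration")
  list(recording = rec, annotations = ann)
}

#' Construct a synchronized EEG + ECG recording container
#'
#' @param eeg channels x samples matrix (microvolts).
#' @param ecg numeric vector (millivolts), same length as `ncol(eeg)`.
#' @param fs shared sampling rate (Hz).
#' @param channel_labels 10-20 labels, one per EEG row.
#' @param montage_xy optional data.frame (`label`,`x`,`y`); defaults to the
#'   built-in montage subset.
#' @param subject_id identifier.
#' @return object of class `physio_recording`.
#' @export
physio_recording <- function(eeg, ecg, fs, channel_labels,
                             montage_xy = NULL, subject_id = "anon") {
  eeg <- as.matrix(eeg)
  stopifnot(length(ecg) == ncol(eeg), length(channel_labels) == nrow(eeg), fs > 0)
  if (is.null(montage_xy)) montage_xy <- montage_1020(channel_labels)
  structure(list(eeg = eeg, ecg = as.numeric(ecg), fs = fs,
                 channel_labels = channel_labels, montage_xy = montage_xy,
                 subject_id = subject_id),
            class = "physio_recording")
}

#' @export
print.physio_recording <- function(x, ...) {
  cat(sprintf("<physio_recording> %s: %d EEG channels + ECG, %.1f s @ %g Hz\n",
              x$subject_id, nrow(x$eeg), ncol(x$eeg) / x$fs, x$fs))
  invisible(x)
}
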