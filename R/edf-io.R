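#' EDF container I/O for recordings
#'
#' Minimal reader/writer for the European Data Format (EDF), the plain
#' 16-bit interchange format most EEG software reads: a 256-byte ASCII
#' header, one 256-byte ASCII block per signal, then fixed-duration data
#' records of little-endian 16-bit integers scaled between per-signal
#' physical and digital ranges. Records are 1 s long; the final record is
#' zero-padded and the true sample count is stored in the header's reserved
#' field so a round trip restores the exact length. Amplitudes survive the
#' round trip to within the 16-bit quantization of each channel's range.
#'
#' @param rec An [eeg_recording()]; `sfreq` must be a whole number.
#' @param path Output `.edf` path.
#' @return `write_edf` returns `path` invisibly; `read_edf` returns an
#'   [eeg_recording()] (without events; see [write_events_tsv()]).
#' @export
write_edf <- function(rec, path) {
  stopifnot(inherits(rec, "eeg_recording"))
  sfreq <- rec$sfreq
  if (abs(sfreq - round(sfreq)) > 1e-9)
    stop("EDF writer requires an integer sampling rate")
  sfreq <- as.integer(round(sfreq))
  ns <- nrow(rec$data)
  n_samples <- ncol(rec$data)
  n_rec <- ceiling(n_samples / sfreq)
  pad_field <- function(x, width)
    formatC(substr(as.character(x), 1, width), width = width, flag = "-")
  phys_max <- pmax(apply(abs(rec$data), 1, max), 1e-6) * 1.0001
  header_bytes <- 256L + 256L * ns
  con <- file(path, "wb")
  on.exit(close(con))
  put <- function(x, width)
    writeChar(paste0(vapply(x, pad_field, character(1), width = width),
                     collapse = ""), con, eos = NULL)
  put("0", 8); put("X X X X", 80); put("Startdate X X X X", 80)
  put("01.01.00", 8); put("00.00.00", 8)
  put(header_bytes, 8)
  put(sprintf("NSAMP=%d", n_samples), 44)
  put(n_rec, 8); put(1, 8); put(ns, 4)
  put(rec$ch_names, 16)
  put(rep("", ns), 80)                       # transducer
  put(rep("uV", ns), 8)                      # physical dimension
  put(formatC(-phys_max, format = "g", digits = 6), 8)
  put(formatC(phys_max, format = "g", digits = 6), 8)
  put(rep(-32768L, ns), 8)
  put(rep(32767L, ns), 8)
  put(rep("", ns), 80)                       # prefiltering
  put(rep(sfreq, ns), 8)
  put(rep("", ns), 32)
  # re-read the header's own physical max (printed at 6 significant digits)
  # so scaling matches what a reader will see
  phys_used <- as.numeric(formatC(phys_max, format = "g", digits = 6))
  padded <- matrix(0, ns, n_rec * sfreq)
  padded[, seq_len(n_samples)] <- rec$data
  for (r in seq_len(n_rec)) {
    idx <- ((r - 1) * sfreq + 1):(r * sfreq)
    for (s in seq_len(ns)) {
      dig <- as.integer(round(padded[s, idx] / phys_used[s] * 32767))
      writeBin(pmax(pmin(dig, 32767L), -32768L), con, size = 2,
               endian = "little")
    }
  }
  invisible(path)
}

#' @rdname write_edf
#' @export
read_edf <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  get <- function(width) trimws(readChar(con, width, useBytes = TRUE))
  get(8); get(80); get(80); get(8); get(8)
  get(8)                                     # header bytes
  reserved <- get(44)
  n_rec <- as.integer(get(8))
  rec_dur <- as.numeric(get(8))
  ns <- as.integer(get(4))
  getv <- function(width) vapply(seq_len(ns), function(i) get(width), character(1))
  labels <- getv(16); getv(80); getv(8)
  pmin_ <- as.numeric(getv(8)); pmax_ <- as.numeric(getv(8))
  dmin <- as.numeric(getv(8)); dmax <- as.numeric(getv(8))
  getv(80)
  spr <- as.integer(getv(8))
  getv(32)
  if (length(unique(spr)) != 1)
    stop("only uniform samples-per-record EDF files are supported")
  sfreq <- spr[1] / rec_dur
  data <- matrix(0, ns, n_rec * spr[1])
  scale <- (pmax_ - pmin_) / (dmax - dmin)
  for (r in seq_len(n_rec)) {
    for (s in seq_len(ns)) {
      dig <- readBin(con, "integer", n = spr[s], size = 2, signed = TRUE,
                     endian = "little")
      idx <- ((r - 1) * spr[s] + 1):(r * spr[s])
      data[s, idx] <- pmin_[s] + (dig - dmin[s]) * scale[s]
    }
  }
  if (grepl("^NSAMP=", reserved)) {
    n_samples <- as.integer(sub("^NSAMP=", "", reserved))
    data <- data[, seq_len(n_samples), drop = FALSE]
  }
  eeg_recording(data, sfreq, labels)
}

#' BIDS-style events sidecar
#'
#' Tab-separated events table with the BIDS core columns `onset`,
#' `duration`, `trial_type` plus task columns `block_delay`, `choice`,
#' `trial_index`, `block_index`; `n/a` encodes missing values.
#'
#' @param events Event data.frame (see [events_from_trials()]).
#' @param path Output `.tsv` path.
#' @return `write_events_tsv` returns `path` invisibly; `read_events_tsv`
#'   returns the event data.frame with internal column names.
#' @export
write_events_tsv <- function(events, path) {
  out <- data.frame(onset = events$onset, duration = events$duration,
                    trial_type = events$kind,
                    block_delay = events$block_delay,
                    choice = ifelse(is.na(events$choice), "n/a", events$choice),
                    trial_index = events$trial_index,
                    block_index = events$block_index)
  out$trial_index[is.na(out$trial_index)] <- "n/a"
  utils::write.table(out, path, sep = "\t", row.names = FALSE, quote = FALSE,
                     na = "n/a", fileEncoding = "UTF-8")
  invisible(path)
}

#' @rdname write_events_tsv
#' @export
read_events_tsv <- function(path) {
  ev <- utils::read.table(path, sep = "\t", header = TRUE, na.strings = "n/a",
                          stringsAsFactors = FALSE, fileEncoding = "UTF-8")
  data.frame(onset = ev$onset, duration = ev$duration, kind = ev$trial_type,
             block_delay = ev$block_delay, choice = ev$choice,
             trial_index = as.integer(ev$trial_index),
             block_index = ev$block_index)
}

#' Write / read a recording plus its events sidecar
#'
#' @param rec An [eeg_recording()].
#' @param dir Directory for the pair of files.
#' @param basename File stem; writes `<stem>.edf` and `<stem>_events.tsv`.
#' @return Paths (writer) or the reassembled [eeg_recording()] (reader).
#' @export
write_recording <- function(rec, dir, basename) {
  edf <- file.path(dir, paste0(basename, ".edf"))
  tsv <- file.path(dir, paste0(basename, "_events.tsv"))
  write_edf(rec, edf)
  if (!is.null(rec$events)) write_events_tsv(rec$events, tsv)
  invisible(c(edf = edf, events = tsv))
}

#' @rdname write_recording
#' @export
read_recording <- function(dir, basename) {
  rec <- read_edf(file.path(dir, paste0(basename, ".edf")))
  tsv <- file.path(dir, paste0(basename, "_events.tsv"))
  if (file.exists(tsv)) rec$events <- read_events_tsv(tsv)
  rec
}
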