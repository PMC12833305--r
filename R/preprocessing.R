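#' Zero-phase band-pass filter
#'
#' Cascaded Butterworth high-pass (order 2) and low-pass (order 6) with
#' zero phase shift. With the default 0.1-40 Hz band the response keeps a
#' 10 Hz component within 1 dB and attenuates 50 Hz mains by more than
#' 20 dB. The recording is reflection-padded before filtering to suppress
#' edge transients of the slow high-pass.
#'
#' Two equivalent implementations are provided: `"fft"` (default) applies
#' the squared Butterworth magnitude response spectrally, which is the
#' frequency response of running the corresponding IIR filters forward and
#' backward, in one FFT pass per channel; `"filtfilt"` runs
#' `signal::filtfilt` in the time domain. Both are zero-phase with the
#' same nominal magnitude response.
#'
#' @param rec An [eeg_recording()].
#' @param low,high Band edges in Hz.
#' @param method `"fft"` or `"filtfilt"`.
#' @return The filtered recording.
#' @export
bandpass_filter <- function(rec, low = 0.1, high = 40,
                            method = c("fft", "filtfilt")) {
  method <- match.arg(method)
  if (rec$sfreq <= 2 * high)
    stop("sampling rate must exceed twice the upper band edge")
  n <- ncol(rec$data)
  pad <- min(round(10 * rec$sfreq), n - 1)
  if (method == "fft") {
    m <- stats::nextn(n + 2 * pad, c(2, 3, 5))
    fbin <- seq(0, m - 1) * rec$sfreq / m
    f <- pmin(fbin, rec$sfreq - fbin)          # physical bin frequency
    # |H_hp|^2 * |H_lp|^2 of Butterworth orders 2 and 6 (forward-backward)
    gain <- (1 / (1 + (low / pmax(f, 1e-12))^(2 * 2))) *
      (1 / (1 + (f / high)^(2 * 6)))
    gain[1] <- 0
    for (ch in seq_len(nrow(rec$data))) {
      x <- rec$data[ch, ]
      xp <- c(rev(x[2:(pad + 1)]), x, rev(x[(n - pad):(n - 1)]))
      xp <- c(xp, numeric(m - length(xp)))
      y <- Re(stats::fft(stats::fft(xp) * gain, inverse = TRUE)) / m
      rec$data[ch, ] <- y[(pad + 1):(pad + n)]
    }
  } else {
    nyq <- rec$sfreq / 2
    hp <- signal::butter(2, low / nyq, type = "high")
    lp <- signal::butter(6, high / nyq, type = "low")
    for (ch in seq_len(nrow(rec$data))) {
      x <- rec$data[ch, ]
      xp <- c(rev(x[2:(pad + 1)]), x, rev(x[(n - pad):(n - 1)]))
      y <- signal::filtfilt(lp, signal::filtfilt(hp, xp))
      rec$data[ch, ] <- y[(pad + 1):(pad + n)]
    }
  }
  rec
}

#' Average re-reference
#'
#' Subtracts, at every sample, the mean across all channels, so the
#' channel-mean of the output is identically zero.
#'
#' @param rec An [eeg_recording()] with at least two channels.
#' @return The re-referenced recording.
#' @export
rereference_average <- function(rec) {
  if (nrow(rec$data) < 2) stop("average reference needs at least 2 channels")
  rec$data <- sweep(rec$data, 2, colMeans(rec$data))
  rec
}

fft_resample_vec <- function(x, n_out) {
  n <- length(x)
  if (n_out == n) return(x)
  # zero-pad to an FFT-friendly length to avoid pathological FFT sizes;
  # the trailing pad maps past the retained output samples
  m <- stats::nextn(n, c(2, 3, 5))
  m_out <- round(m * n_out / n)
  X <- stats::fft(c(x, numeric(m - n)))
  Y <- complex(m_out)
  half <- min(m, m_out) %/% 2
  Y[1:(half + 1)] <- X[1:(half + 1)]
  if (half > 1) Y[(m_out - half + 2):m_out] <- X[(m - half + 2):m]
  # keep a real signal if the shared Nyquist bin is hit
  if (min(m, m_out) %% 2 == 0) Y[half + 1] <- Re(Y[half + 1])
  Re(stats::fft(Y, inverse = TRUE))[seq_len(n_out)] / m
}

#' Resample a recording
#'
#' Fourier-domain resampling: the spectrum is truncated (or zero-padded) to
#' the target rate and inverted, which preserves the frequency and
#' amplitude of in-band components exactly for band-limited input. Event
#' onsets are stored in seconds and therefore unchanged.
#'
#' @param rec An [eeg_recording()].
#' @param target Target sampling rate in Hz, below the current rate.
#' @return The resampled recording.
#' @export
resample_recording <- function(rec, target = 250) {
  if (target >= rec$sfreq) stop("target rate must be below the current rate")
  n <- ncol(rec$data)
  n_out <- round(n * target / rec$sfreq)
  out <- matrix(0, nrow(rec$data), n_out)
  for (ch in seq_len(nrow(rec$data)))
    out[ch, ] <- fft_resample_vec(rec$data[ch, ], n_out)
  rec$data <- out
  rec$sfreq <- target
  rec
}

#' Epoch container
#'
#' @param kind `"feedback"` or `"delay"`.
#' @param data Epochs x channels x samples array, microvolts.
#' @param times Sample times in seconds relative to the lock point.
#' @param metadata One row per epoch (choice, block delay, indices, ...).
#' @param sfreq Sampling rate, Hz.
#' @param ch_names Channel labels.
#' @param rejected_count Epochs removed by amplitude rejection so far.
#' @return An object of class `epoch_set`.
#' @export
epoch_set <- function(kind, data, times, metadata, sfreq, ch_names,
                      rejected_count = 0L) {
  stopifnot(length(dim(data)) == 3, dim(data)[3] == length(times),
            dim(data)[2] == length(ch_names))
  structure(list(kind = kind, data = data, times = times,
                 metadata = metadata, sfreq = sfreq, ch_names = ch_names,
                 rejected_count = rejected_count),
            class = "epoch_set")
}

#' @export
print.epoch_set <- function(x, ...) {
  cat(sprintf("<epoch_set:%s> %d epochs x %d channels x %d samples @ %g Hz (%d rejected)\n",
              x$kind, dim(x$data)[1], dim(x$data)[2], dim(x$data)[3],
              x$sfreq, x$rejected_count))
  invisible(x)
}

#' Number of epochs in an epoch set
#' @param es An [epoch_set()].
#' @return Integer count.
#' @export
n_epochs <- function(es) dim(es$data)[1]

#' Subset an epoch set by epochs and/or channels
#' @param es An [epoch_set()].
#' @param epochs Integer/logical epoch index, or `NULL` to keep all.
#' @param channels Channel labels to keep, or `NULL`; an absent channel is
#'   an error naming it.
#' @return The reduced [epoch_set()].
#' @export
subset_epochs <- function(es, epochs = NULL, channels = NULL) {
  if (!is.null(epochs)) {
    es$data <- es$data[epochs, , , drop = FALSE]
    es$metadata <- es$metadata[epochs, , drop = FALSE]
  }
  if (!is.null(channels)) {
    idx <- match(channels, es$ch_names)
    if (anyNA(idx))
      stop("missing channel(s): ",
           paste(channels[is.na(idx)], collapse = ", "))
    es$data <- es$data[, idx, , drop = FALSE]
    es$ch_names <- channels
  }
  es
}

slice_window <- function(rec, start_s, n_samp) {
  i0 <- floor(start_s * rec$sfreq + 1e-9) + 1
  if (i0 < 1 || i0 + n_samp - 1 > ncol(rec$data)) return(NULL)
  rec$data[, i0:(i0 + n_samp - 1), drop = FALSE]
}

#' Feedback-locked epochs
#'
#' Extracts one `[tmin, tmax]` epoch per feedback event, time zero at the
#' feedback-cue onset. Because SS choices are rare for the cohorts of
#' interest, only LL-choice feedback is kept by default. Events whose
#' window is not fully inside the recording are dropped with a warning.
#'
#' @param rec A preprocessed [eeg_recording()] with an event table.
#' @param tmin,tmax Epoch window in seconds relative to feedback onset.
#' @param ll_only Keep only LL-choice feedback events.
#' @return An [epoch_set()] of kind `"feedback"`.
#' @export
extract_feedback_epochs <- function(rec, tmin = -1, tmax = 2, ll_only = TRUE) {
  ev <- rec$events[rec$events$kind == "feedback", , drop = FALSE]
  if (ll_only) ev <- ev[ev$choice == "LL", , drop = FALSE]
  n_samp <- round((tmax - tmin) * rec$sfreq)
  times <- tmin + (seq_len(n_samp) - 1) / rec$sfreq
  slices <- list(); meta <- list()
  dropped <- 0L
  for (i in seq_len(nrow(ev))) {
    sl <- slice_window(rec, ev$onset[i] + tmin, n_samp)
    if (is.null(sl)) { dropped <- dropped + 1L; next }
    slices[[length(slices) + 1]] <- sl
    meta[[length(meta) + 1]] <- ev[i, c("choice", "block_delay",
                                        "trial_index", "block_index")]
  }
  if (dropped > 0)
    warning(dropped, " feedback epoch(s) outside the recording were dropped")
  data <- array(0, c(length(slices), nrow(rec$data), n_samp))
  for (i in seq_along(slices)) data[i, , ] <- slices[[i]]
  metadata <- if (length(meta)) do.call(rbind, meta) else
    data.frame(choice = character(0), block_delay = numeric(0),
               trial_index = integer(0), block_index = integer(0))
  epoch_set("feedback", data, times, metadata, rec$sfreq, rec$ch_names)
}

#' Overlapping 1-s epochs of the waiting period
#'
#' Segments each actually-waited delay interval of the 7/15/30-s blocks
#' into `win`-second windows advancing by `win * (1 - overlap)` seconds: a
#' waited interval of length T yields `floor((T - win) / step) + 1`
#' windows (13 for a full 7-s wait, 59 for 30 s). The 1-s block never
#' contributes. Aborted waits contribute only the windows that fit.
#'
#' @param rec A preprocessed [eeg_recording()] with an event table.
#' @param win Window length, seconds.
#' @param overlap Fractional overlap between consecutive windows.
#' @param delays Block delays (seconds) whose waiting periods are analysed.
#' @return An [epoch_set()] of kind `"delay"`; `times` start at 0 within
#'   each window.
#' @export
segment_delay_epochs <- function(rec, win = 1, overlap = 0.5,
                                 delays = c(7, 15, 30)) {
  ev <- delay_periods(rec$events, delays)
  step <- win * (1 - overlap)
  n_samp <- round(win * rec$sfreq)
  times <- (seq_len(n_samp) - 1) / rec$sfreq
  slices <- list(); meta <- list()
  for (i in seq_len(nrow(ev))) {
    T_wait <- ev$duration[i]
    if (T_wait < win - 1e-9) next
    k_max <- floor((T_wait - win) / step + 1e-9)
    for (k in 0:k_max) {
      sl <- slice_window(rec, ev$onset[i] + k * step, n_samp)
      if (is.null(sl)) next
      slices[[length(slices) + 1]] <- sl
      meta[[length(meta) + 1]] <- data.frame(
        choice = ev$choice[i], block_delay = ev$block_delay[i],
        trial_index = ev$trial_index[i], block_index = ev$block_index[i],
        window_index = k)
    }
  }
  data <- array(0, c(length(slices), nrow(rec$data), n_samp))
  for (i in seq_along(slices)) data[i, , ] <- slices[[i]]
  metadata <- if (length(meta)) do.call(rbind, meta) else
    data.frame(choice = character(0), block_delay = numeric(0),
               trial_index = integer(0), block_index = integer(0),
               window_index = integer(0))
  epoch_set("delay", data, times, metadata, rec$sfreq, rec$ch_names)
}

#' Amplitude-based epoch rejection
#'
#' Drops every epoch whose peak absolute amplitude on any channel strictly
#' exceeds the threshold; an epoch peaking exactly at the threshold is
#' retained.
#'
#' @param es An [epoch_set()] in microvolts.
#' @param threshold Rejection threshold, microvolts.
#' @return The [epoch_set()] with offending epochs removed and
#'   `rejected_count` incremented.
#' @export
reject_epochs <- function(es, threshold = 150) {
  if (n_epochs(es) == 0) return(es)
  peak <- apply(abs(es$data), 1, max)
  keep <- peak <= threshold
  out <- subset_epochs(es, epochs = which(keep))
  out$rejected_count <- es$rejected_count + sum(!keep)
  out
}

#' Participant inclusion rules
#'
#' A participant enters the feedback (theta/delta) analysis with at least
#' 12 retained LL feedback epochs, and the anticipatory alpha analysis with
#' at least one retained waiting-period epoch from the 7/15/30-s blocks.
#'
#' @param counts Data.frame with columns `participant_id`, `n_feedback`,
#'   `n_delay`.
#' @return The data.frame with logical columns `include_feedback` and
#'   `include_alpha` appended.
#' @export
apply_inclusion_rules <- function(counts) {
  counts$include_feedback <- counts$n_feedback >= 12
  counts$include_alpha <- counts$n_delay >= 1
  counts
}

#' Standard preprocessing chain
#'
#' Band-pass filter, average re-reference, and resampling, in that order;
#' epoching and rejection are applied afterwards by the epoch extractors.
#' An optional cleaning callback slots in after re-referencing for external
#' artifact-removal schemes (component-based cleaning is manual in practice
#' and therefore not built in).
#'
#' @param rec An [eeg_recording()].
#' @param low,high Band edges, Hz.
#' @param target Resampling target rate, Hz (`NULL` to skip).
#' @param cleaner Optional `function(rec) -> rec` applied after
#'   re-referencing.
#' @return The preprocessed recording.
#' @export
preprocess_recording <- function(rec, low = 0.1, high = 40, target = 250,
                                 cleaner = NULL) {
  rec <- bandpass_filter(rec, low, high)
  rec <- rereference_average(rec)
  if (!is.null(cleaner)) rec <- cleaner(rec)
  if (!is.null(target) && target < rec$sfreq)
    rec <- resample_recording(rec, target)
  rec
}
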