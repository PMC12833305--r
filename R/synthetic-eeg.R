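#' Synthetic EEG generator configuration
#'
#' Parameters of the synthetic multichannel EEG that carries the structure
#' the analysis pipeline assumes: a 1/f ("pink") background, an anticipatory
#' alpha oscillation at POz whose amplitude is an affine, typically
#' decreasing, function of the discounting factor, feedback-locked
#' fronto-central theta and centro-parietal delta bursts, and occasional
#' high-amplitude square artifacts that exercise the rejection path. The
#' scalp profile is schematic (full alpha at POz, half at Pz/Oz, bursts only
#' on their named clusters); no head-model forward simulation is attempted.
#'
#' @param sfreq Sampling rate in Hz.
#' @param channels Channel labels (10-10 names); must include Fz, FC1, FC2,
#'   Cz, CPz, Pz, POz.
#' @param background_exponent Spectral slope of the background (power
#'   ~ 1/f^exponent).
#' @param background_rms Background RMS amplitude per channel, microvolts.
#' @param alpha_freq Anticipatory oscillation frequency, Hz.
#' @param alpha_base_amp Alpha amplitude at DF = 0, microvolts.
#' @param alpha_df_slope Change in alpha amplitude per unit DF, microvolts
#'   (negative reproduces the higher-alpha-in-impulsive direction); the
#'   resulting amplitude is clamped at 0.
#' @param theta_freq,delta_freq Burst carrier frequencies, Hz.
#' @param burst_amp Burst peak amplitude, microvolts.
#' @param theta_window,delta_window Post-feedback burst windows, seconds.
#' @param ll_only_bursts Inject bursts only on LL-choice feedback (default).
#' @param artifact_rate Artifacts per minute.
#' @param artifact_amp Artifact amplitude in microvolts; must exceed the
#'   150 microvolt rejection threshold to be useful.
#' @param artifact_duration Artifact length, seconds.
#' @return An object of class `eeg_gen_config`.
#' @export
eeg_gen_config <- function(sfreq = 500,
                           channels = c("Fz", "FC1", "FC2", "Cz", "CPz",
                                        "Pz", "POz", "Oz"),
                           background_exponent = 1,
                           background_rms = 10,
                           alpha_freq = 10,
                           alpha_base_amp = 4,
                           alpha_df_slope = -3,
                           theta_freq = 6,
                           delta_freq = 2,
                           burst_amp = 6,
                           theta_window = c(0.2, 0.4),
                           delta_window = c(0.1, 0.6),
                           ll_only_bursts = TRUE,
                           artifact_rate = 0.5,
                           artifact_amp = 400,
                           artifact_duration = 0.2) {
  required <- c("Fz", "FC1", "FC2", "Cz", "CPz", "Pz", "POz")
  missing <- setdiff(required, channels)
  if (length(missing) > 0)
    stop("channel montage is missing: ", paste(missing, collapse = ", "))
  stopifnot(sfreq > 0, background_rms >= 0, alpha_base_amp >= 0,
            burst_amp >= 0, artifact_rate >= 0)
  if (artifact_amp <= 150)
    stop("artifact_amp must exceed the 150 uV rejection threshold")
  structure(as.list(environment())[c(
    "sfreq", "channels", "background_exponent", "background_rms",
    "alpha_freq", "alpha_base_amp", "alpha_df_slope", "theta_freq",
    "delta_freq", "burst_amp", "theta_window", "delta_window",
    "ll_only_bursts", "artifact_rate", "artifact_amp", "artifact_duration")],
    class = "eeg_gen_config")
}

#' Multichannel EEG recording container
#'
#' @param data Channels x samples numeric matrix, microvolts.
#' @param sfreq Sampling rate, Hz.
#' @param ch_names Channel labels, one per row of `data`.
#' @param events Event table data.frame (see [events_from_trials()]).
#' @return An object of class `eeg_recording`.
#' @export
eeg_recording <- function(data, sfreq, ch_names, events = NULL) {
  stopifnot(is.matrix(data), nrow(data) == length(ch_names), sfreq > 0,
            all(is.finite(data)))
  structure(list(data = data, sfreq = sfreq, ch_names = ch_names,
                 events = events),
            class = "eeg_recording")
}

#' @export
print.eeg_recording <- function(x, ...) {
  cat(sprintf("<eeg_recording> %d channels x %d samples @ %g Hz (%.1f s), %d events\n",
              nrow(x$data), ncol(x$data), x$sfreq,
              ncol(x$data) / x$sfreq,
              if (is.null(x$events)) 0L else nrow(x$events)))
  invisible(x)
}

#' Event table from a behavioral trial log
#'
#' Reconstructs the session timeline implied by the trial log: per block a
#' `block_start` marker followed by the full-delay demonstrations, then per
#' trial a `delay_start` event lasting the actual waited interval and a
#' `feedback` event after the 1-s choice highlight.
#'
#' @param trials Trial data.frame as produced by [run_session()] (`$trials`).
#' @param cfg The [task_config()] the log was produced under.
#' @return Data.frame with columns `onset`, `duration`, `kind`,
#'   `block_delay`, `choice`, `trial_index`, `block_index`; onsets
#'   non-decreasing.
#' @export
events_from_trials <- function(trials, cfg = task_config()) {
  rows <- list()
  t <- 0
  for (b in sort(unique(trials$block_index))) {
    tr <- trials[trials$block_index == b, , drop = FALSE]
    delay <- tr$delay[1]
    rows[[length(rows) + 1]] <- data.frame(
      onset = t, duration = cfg$demo_repeats * delay, kind = "block_start",
      block_delay = delay, choice = NA_character_, trial_index = NA_integer_,
      block_index = b)
    t <- t + cfg$demo_repeats * delay
    for (i in seq_len(nrow(tr))) {
      rows[[length(rows) + 1]] <- data.frame(
        onset = t, duration = tr$wait_elapsed[i], kind = "delay_start",
        block_delay = delay, choice = tr$choice[i],
        trial_index = tr$trial_index[i], block_index = b)
      fb_onset <- t + tr$wait_elapsed[i] + cfg$highlight_duration
      rows[[length(rows) + 1]] <- data.frame(
        onset = fb_onset, duration = cfg$feedback_duration, kind = "feedback",
        block_delay = delay, choice = tr$choice[i],
        trial_index = tr$trial_index[i], block_index = b)
      t <- t + tr$trial_duration[i]
    }
  }
  do.call(rbind, rows)
}

#' 1/f background noise
#'
#' Zero-mean noise whose power spectrum falls as 1/f^exponent, generated by
#' spectrally shaping white noise in the frequency domain, independently per
#' channel, then scaled to the requested RMS.
#'
#' @param n_channels,n_samples Output dimensions.
#' @param sfreq Sampling rate, Hz.
#' @param exponent Spectral exponent (0 = white noise).
#' @param rms Target root-mean-square amplitude per channel.
#' @return Channels x samples matrix.
#' @export
generate_background <- function(n_channels, n_samples, sfreq,
                                exponent = 1, rms = 10) {
  stopifnot(n_samples > 0, n_channels > 0)
  out <- matrix(0, n_channels, n_samples)
  # synthesize at an FFT-friendly length and truncate (noise statistics are
  # unaffected; avoids pathological mixed-radix FFT sizes)
  m <- stats::nextn(n_samples, c(2, 3, 5))
  freqs <- seq(0, m - 1) * sfreq / m
  f_phys <- pmin(freqs, sfreq - freqs)
  gain <- c(0, f_phys[-1]^(-exponent / 2))
  for (ch in seq_len(n_channels)) {
    w <- stats::rnorm(m)
    x <- Re(stats::fft(stats::fft(w) * gain, inverse = TRUE))[seq_len(n_samples)] / m
    s <- stats::sd(x)
    out[ch, ] <- if (s > 0) x * (rms / s) else x
  }
  out
}

delay_periods <- function(events, delays = c(7, 15, 30)) {
  ev <- events[events$kind == "delay_start" &
                 events$block_delay %in% delays, , drop = FALSE]
  ev[ev$duration > 0, , drop = FALSE]
}

#' Inject anticipatory alpha at POz
#'
#' Adds a fixed-frequency sinusoid, with an independent random phase per
#' delay period (anticipatory alpha is non-phase-locked power), during each
#' waiting interval of the 7/15/30-s blocks. Amplitude is
#' `max(0, alpha_base_amp + alpha_df_slope * df)` at POz, halved at Pz and
#' Oz (when present), zero elsewhere.
#'
#' @param rec An [eeg_recording()] with `delay_start` events.
#' @param df The participant's discounting factor in `[0, 1]`.
#' @param gcfg An [eeg_gen_config()].
#' @return The recording with alpha added.
#' @export
inject_anticipatory_alpha <- function(rec, df, gcfg = eeg_gen_config()) {
  stopifnot(df >= 0, df <= 1)
  amp <- max(0, gcfg$alpha_base_amp + gcfg$alpha_df_slope * df)
  if (amp == 0) return(rec)
  targets <- c(POz = 1, Pz = 0.5, Oz = 0.5)
  targets <- targets[names(targets) %in% rec$ch_names]
  ev <- delay_periods(rec$events)
  n <- ncol(rec$data)
  for (i in seq_len(nrow(ev))) {
    i0 <- floor(ev$onset[i] * rec$sfreq) + 1
    i1 <- min(n, floor((ev$onset[i] + ev$duration[i]) * rec$sfreq))
    if (i1 < i0) next
    tt <- (seq(i0, i1) - 1) / rec$sfreq
    phase <- stats::runif(1, 0, 2 * pi)
    wave <- sin(2 * pi * gcfg$alpha_freq * tt + phase)
    for (chn in names(targets)) {
      ch <- match(chn, rec$ch_names)
      rec$data[ch, i0:i1] <- rec$data[ch, i0:i1] + amp * targets[[chn]] * wave
    }
  }
  rec
}

hann_window <- function(n) {
  if (n == 1) return(1)
  0.5 - 0.5 * cos(2 * pi * seq(0, n - 1) / (n - 1))
}

#' Inject feedback-locked theta and delta bursts
#'
#' Adds Hann-windowed oscillatory bursts after each feedback event: theta
#' over the fronto-central cluster (Fz, FC1, FC2) in the configured
#' post-feedback window and delta over the centro-parietal cluster (Cz,
#' CPz). By default only LL-choice feedback gets bursts, mirroring the
#' restriction of the feedback analysis to LL trials.
#'
#' @inheritParams inject_anticipatory_alpha
#' @return The recording with bursts added.
#' @export
inject_feedback_bursts <- function(rec, gcfg = eeg_gen_config()) {
  if (gcfg$burst_amp == 0) return(rec)
  ev <- rec$events[rec$events$kind == "feedback", , drop = FALSE]
  if (isTRUE(gcfg$ll_only_bursts))
    ev <- ev[ev$choice == "LL", , drop = FALSE]
  if (nrow(ev) == 0) return(rec)
  n <- ncol(rec$data)
  specs <- list(
    list(chs = c("Fz", "FC1", "FC2"), f = gcfg$theta_freq,
         win = gcfg$theta_window),
    list(chs = c("Cz", "CPz"), f = gcfg$delta_freq, win = gcfg$delta_window))
  for (i in seq_len(nrow(ev))) {
    for (sp in specs) {
      i0 <- floor((ev$onset[i] + sp$win[1]) * rec$sfreq) + 1
      i1 <- min(n, floor((ev$onset[i] + sp$win[2]) * rec$sfreq))
      if (i1 < i0) next
      tt <- (seq(i0, i1) - 1) / rec$sfreq
      phase <- stats::runif(1, 0, 2 * pi)
      burst <- gcfg$burst_amp * hann_window(i1 - i0 + 1) *
        sin(2 * pi * sp$f * tt + phase)
      for (chn in sp$chs) {
        ch <- match(chn, rec$ch_names)
        rec$data[ch, i0:i1] <- rec$data[ch, i0:i1] + burst
      }
    }
  }
  rec
}

#' Inject high-amplitude square artifacts
#'
#' Adds square pulses of `artifact_amp` microvolts at Poisson-distributed
#' times on random single channels, so that the downstream amplitude
#' rejection has something to reject.
#'
#' @inheritParams inject_anticipatory_alpha
#' @return The recording with artifacts added; attribute
#'   `"artifact_onsets"` lists their onset times (seconds).
#' @export
inject_artifacts <- function(rec, gcfg = eeg_gen_config()) {
  dur_min <- ncol(rec$data) / rec$sfreq / 60
  n_art <- stats::rpois(1, gcfg$artifact_rate * dur_min)
  onsets <- numeric(0)
  if (n_art > 0) {
    n <- ncol(rec$data)
    len <- max(1, round(gcfg$artifact_duration * rec$sfreq))
    for (a in seq_len(n_art)) {
      i0 <- sample.int(max(1, n - len), 1)
      ch <- sample.int(nrow(rec$data), 1)
      rec$data[ch, i0:(i0 + len - 1)] <- rec$data[ch, i0:(i0 + len - 1)] +
        gcfg$artifact_amp
      onsets <- c(onsets, (i0 - 1) / rec$sfreq)
    }
  }
  attr(rec, "artifact_onsets") <- onsets
  rec
}

#' Synthesize a full-session EEG recording from a behavioral log
#'
#' Assembles background + anticipatory alpha + feedback bursts + artifacts
#' on the timeline implied by the trial log, with an event table consistent
#' with the log's trial timing. Fully reproducible for a fixed seed.
#'
#' @param trials Trial data.frame (one session) as from [run_session()].
#' @param df The session's discounting factor (drives the alpha amplitude).
#' @param gcfg An [eeg_gen_config()].
#' @param cfg The [task_config()] the log was produced under.
#' @param seed Integer seed.
#' @param pad Seconds of background appended after the last event.
#' @return An [eeg_recording()].
#' @export
synthesize_session <- function(trials, df, gcfg = eeg_gen_config(),
                               cfg = task_config(), seed = 1, pad = 3) {
  set.seed(seed)
  events <- events_from_trials(trials, cfg)
  total <- max(events$onset + events$duration) + pad
  n_samples <- ceiling(total * gcfg$sfreq)
  data <- generate_background(length(gcfg$channels), n_samples, gcfg$sfreq,
                              gcfg$background_exponent, gcfg$background_rms)
  rec <- eeg_recording(data, gcfg$sfreq, gcfg$channels, events)
  rec <- inject_anticipatory_alpha(rec, df, gcfg)
  rec <- inject_feedback_bursts(rec, gcfg)
  rec <- inject_artifacts(rec, gcfg)
  rec
}
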