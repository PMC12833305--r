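# Small programmatic fixtures shared across test files.

# epoch set holding identical pure-tone epochs
tone_epochs <- function(freq = 10, amp = 1, sfreq = 250, n_ep = 3,
                        dur = 3, tmin = -1, ch_names = c("Fz", "POz"),
                        kind = "feedback") {
  ns <- round(dur * sfreq)
  times <- tmin + (seq_len(ns) - 1) / sfreq
  x <- amp * sin(2 * pi * freq * times)
  data <- array(0, c(n_ep, length(ch_names), ns))
  for (e in seq_len(n_ep)) for (ch in seq_along(ch_names)) data[e, ch, ] <- x
  epoch_set(kind, data, times,
            data.frame(choice = rep("LL", n_ep), block_delay = 7,
                       trial_index = seq_len(n_ep) - 1L, block_index = 0L),
            sfreq, ch_names)
}

# recording with scripted delay_start / feedback events over silence
scripted_recording <- function(events, dur, sfreq = 250,
                               ch_names = c("Fz", "FC1", "FC2", "Cz",
                                            "CPz", "Pz", "POz", "Oz"),
                               data = NULL) {
  n <- round(dur * sfreq)
  if (is.null(data)) data <- matrix(0, length(ch_names), n)
  eeg_recording(data, sfreq, ch_names, events)
}

event_row <- function(onset, duration, kind, block_delay = 7,
                      choice = "LL", trial_index = 0L, block_index = 0L) {
  data.frame(onset = onset, duration = duration, kind = kind,
             block_delay = block_delay, choice = choice,
             trial_index = trial_index, block_index = block_index)
}

# independent fine-grid area oracle for the discounting factor: linear
# interpolation of the curve evaluated on a 1e4-point grid augmented with
# the knots, integrated by the composite trapezoid rule
df_area_oracle <- function(delays, nips, n_grid = 1e4) {
  o <- order(delays)
  x <- delays[o]; y <- nips[o]
  grid <- sort(unique(c(seq(min(x), max(x), length.out = n_grid), x)))
  yy <- approx(x, y, xout = grid)$y
  sum(diff(grid) * (yy[-length(yy)] + yy[-1]) / 2) / (max(x) - min(x))
}
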