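test_that("Morlet power localizes pure tones and scales quadratically", {
  es <- tone_epochs(freq = 10, amp = 1, n_ep = 2, dur = 3)
  tfr <- morlet_tfr(es, freqs = 2:20)
  # collapse to a frequency profile away from the epoch edges
  sel <- tfr$times > -0.3 & tfr$times < 1.3
  prof <- apply(tfr$power[, 1, , sel], 2, mean)
  expect_equal(tfr$freqs[which.max(prof)], 10)
  # power convention: amplitude a reads a^2 at the tone frequency
  expect_equal(max(prof), 1, tolerance = 0.05)
  es2 <- tone_epochs(freq = 10, amp = 2, n_ep = 2, dur = 3)
  tfr2 <- morlet_tfr(es2, freqs = 2:20)
  expect_equal(tfr2$power[1, 1, , sel] / tfr$power[1, 1, , sel],
               array(4, dim(tfr$power[1, 1, , sel])), tolerance = 1e-6)
  # silence in, silence out
  es0 <- tone_epochs(freq = 10, amp = 0)
  expect_equal(max(morlet_tfr(es0, freqs = 2:20)$power), 0)
  expect_error(morlet_tfr(es, freqs = c(10, 200)), "Nyquist")
})

test_that("Morlet power tracks the instantaneous frequency of a chirp", {
  sfreq <- 250; dur <- 8
  tt <- (seq_len(dur * sfreq) - 1) / sfreq
  f0 <- 5; f1 <- 25
  x <- sin(2 * pi * (f0 * tt + (f1 - f0) / (2 * dur) * tt^2))
  data <- array(0, c(1, 1, length(x))); data[1, 1, ] <- x
  es <- epoch_set("delay", data, tt, data.frame(block_delay = 7), sfreq, "POz")
  tfr <- morlet_tfr(es, freqs = 3:30)
  sel <- which(tfr$times > 1 & tfr$times < 7)
  path <- tfr$freqs[apply(tfr$power[1, 1, , sel], 2, which.max)]
  # monotone ridge, allowing for discrete frequency steps
  expect_true(all(diff(path) >= 0))
  expect_gt(path[length(path)], path[1] + 10)
})

test_that("baseline correction returns decibels relative to the pre-event window", {
  sfreq <- 250
  times <- -1 + (seq_len(3 * sfreq) - 1) / sfreq
  # stationary tone: 0 dB everywhere after correction
  x <- sin(2 * pi * 10 * times)
  data <- array(0, c(1, 1, length(x))); data[1, 1, ] <- x
  es <- epoch_set("feedback", data, times, data.frame(choice = "LL"), sfreq, "Fz")
  tfr <- baseline_correct(morlet_tfr(es, freqs = 8:12))
  expect_equal(tfr$baseline_mode, "logratio")
  sel <- tfr$times > 0.2 & tfr$times < 1.5
  expect_equal(mean(tfr$power[1, 1, 3, sel]), 0, tolerance = 0.1)
  # amplitude step of sqrt(2) at t = 0 doubles power: +3.01 dB
  x2 <- x * ifelse(times >= 0, sqrt(2), 1)
  data[1, 1, ] <- x2
  es2 <- epoch_set("feedback", data, times, data.frame(choice = "LL"), sfreq, "Fz")
  tfr2 <- baseline_correct(morlet_tfr(es2, freqs = 8:12))
  expect_equal(mean(tfr2$power[1, 1, 3, sel]), 10 * log10(2),
               tolerance = 0.15)
  expect_error(baseline_correct(morlet_tfr(es, freqs = 8:12),
                                window = c(-3, -2.5)),
               "no samples")
})

test_that("cluster band power isolates an injected burst", {
  gcfg <- eeg_gen_config(sfreq = 250, background_rms = 0.5, burst_amp = 4,
                         artifact_rate = 0)
  mk <- function(with_burst) {
    set.seed(31)
    rec <- waitworth:::mini_feedback_recording(
      8, if (with_burst) gcfg else eeg_gen_config(
        sfreq = 250, background_rms = 0.5, burst_amp = 0, artifact_rate = 0))
    extract_feedback_epochs(rec)
  }
  tfr_b <- suppressWarnings(baseline_correct(morlet_tfr(mk(TRUE), freqs = 1:10)))
  tfr_0 <- suppressWarnings(baseline_correct(morlet_tfr(mk(FALSE), freqs = 1:10)))
  theta_b <- extract_band_window_power(tfr_b, c(4, 7), c("Fz", "FC1", "FC2"),
                                       c(0.2, 0.4))
  theta_0 <- extract_band_window_power(tfr_0, c(4, 7), c("Fz", "FC1", "FC2"),
                                       c(0.2, 0.4))
  expect_gt(theta_b, theta_0 + 3)
  # the grand-average theta maximum falls inside the injection window
  prof <- apply(tfr_b$power[, 1:3, 4:7, , drop = FALSE], 4, mean)
  tmax <- tfr_b$times[which.max(prof)]
  expect_gt(tmax, 0.15); expect_lt(tmax, 0.45)
  delta_b <- extract_band_window_power(tfr_b, c(1, 3), c("Cz", "CPz"),
                                       c(0.1, 0.6))
  expect_gt(delta_b, 1)
  expect_error(extract_band_window_power(tfr_b, c(4, 7), c("Fz", "FC9"),
                                         c(0.2, 0.4)),
               "FC9")
})

test_that("the Hann periodogram integrates to the signal power", {
  sfreq <- 250
  tt <- (seq_len(sfreq) - 1) / sfreq
  a <- 3
  x <- a * sin(2 * pi * 10 * tt)
  pg <- psd_periodogram(x, sfreq)
  total <- sum(pg$psd) * (pg$freq[2] - pg$freq[1])
  expect_equal(total, a^2 / 2, tolerance = 0.1)
  # white noise: flat density at 2 sigma^2 / fs (one-sided)
  set.seed(8)
  es_n <- tone_epochs(amp = 0, n_ep = 200, dur = 1, tmin = 0,
                      ch_names = "POz", kind = "delay")
  es_n$data[] <- rnorm(length(es_n$data), sd = 2)
  flat <- compute_alpha_psd(es_n, channel = "POz", band = c(8, 12))
  expect_equal(flat, 2 * 4 / sfreq, tolerance = 0.15)
  # silence
  es_z <- tone_epochs(amp = 0, n_ep = 3, dur = 1, tmin = 0, ch_names = "POz",
                      kind = "delay")
  expect_equal(compute_alpha_psd(es_z, channel = "POz"), 0)
})

test_that("alpha PSD matches the analytic sinusoid oracle and is stable in epoch count", {
  sfreq <- 250; a <- 1.5
  # overlapping 1-s epochs cut from one long tone + noise recording
  set.seed(12)
  ev <- event_row(2, 40, "delay_start", block_delay = 30)
  tt <- (seq_len(45 * sfreq) - 1) / sfreq
  x <- a * sin(2 * pi * 10 * tt) + rnorm(length(tt), sd = 0.5)
  rec <- scripted_recording(ev, dur = 45, sfreq = sfreq, ch_names = "POz",
                            data = matrix(x, 1))
  es <- segment_delay_epochs(rec, delays = 30)
  psd <- compute_alpha_psd(es, band = c(8, 12))
  # band-integrated tone power a^2/2 plus the noise floor, spread over the
  # 5 alpha-band bins
  noise_floor <- 2 * 0.25 / sfreq
  expected <- (a^2 / 2) / 5 + noise_floor
  expect_equal(psd, expected, tolerance = 0.1)
  # subsampling epochs leaves the estimate unbiased
  half <- subset_epochs <- es
  half$data <- es$data[seq(1, n_epochs(es), by = 2), , , drop = FALSE]
  half$metadata <- es$metadata[seq(1, n_epochs(es), by = 2), , drop = FALSE]
  expect_equal(compute_alpha_psd(half, band = c(8, 12)), psd,
               tolerance = 0.15)
  # per-level output splits by block delay
  lv <- compute_alpha_psd(es, by_level = TRUE)
  expect_equal(lv$delay_level, 30)
  expect_equal(lv$n_epochs, n_epochs(es))
  expect_error(compute_alpha_psd(es, channel = "Qz"), "Qz")
})
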