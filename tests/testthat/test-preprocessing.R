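make_tone_rec <- function(freqs_amp, dur = 60, sfreq = 500, n_ch = 2,
                          dc = 0) {
  t <- (seq_len(dur * sfreq) - 1) / sfreq
  x <- dc + rowSums(sapply(seq_len(nrow(freqs_amp)), function(i)
    freqs_amp[i, 2] * sin(2 * pi * freqs_amp[i, 1] * t)))
  eeg_recording(matrix(rep(x, n_ch), nrow = n_ch, byrow = TRUE), sfreq,
                paste0("ch", seq_len(n_ch)))
}

mid <- function(x, frac = c(0.25, 0.75)) {
  n <- length(x)
  x[round(frac[1] * n):round(frac[2] * n)]
}

test_that("band-pass keeps alpha, kills DC, and attenuates mains", {
  rec10 <- make_tone_rec(cbind(10, 1))
  f10 <- bandpass_filter(rec10)
  expect_equal(max(abs(mid(f10$data[1, ]))), 1, tolerance = 0.05)
  recdc <- make_tone_rec(cbind(10, 0), dc = 5)
  fdc <- bandpass_filter(recdc)
  expect_lt(max(abs(mid(fdc$data[1, ]))), 0.05)
  rec50 <- make_tone_rec(cbind(50, 1))
  f50 <- bandpass_filter(rec50)
  expect_lt(max(abs(mid(f50$data[1, ]))), 0.1)
  expect_error(bandpass_filter(eeg_recording(matrix(0, 1, 100), 60, "a")),
               "sampling rate")
  # the spectral and time-domain implementations agree
  ft <- bandpass_filter(rec10, method = "filtfilt")
  expect_equal(mid(f10$data[1, ]), mid(ft$data[1, ]), tolerance = 0.01)
})

test_that("average reference zeroes the channel mean and is idempotent", {
  set.seed(6)
  rec <- eeg_recording(matrix(rnorm(5 * 1000), 5), 250, paste0("c", 1:5))
  rr <- rereference_average(rec)
  expect_lt(max(abs(colMeans(rr$data))), 1e-10)
  expect_equal(rereference_average(rr)$data, rr$data, tolerance = 1e-12)
  # an already zero-mean pair is unchanged; identical channels vanish
  pm <- eeg_recording(rbind(rep(1, 10), rep(-1, 10)), 100, c("a", "b"))
  expect_equal(rereference_average(pm)$data, pm$data)
  same <- eeg_recording(rbind(sin(1:100), sin(1:100)), 100, c("a", "b"))
  expect_equal(max(abs(rereference_average(same)$data)), 0)
  expect_error(rereference_average(eeg_recording(matrix(0, 1, 10), 100, "a")),
               "2 channels")
})

test_that("filtering and re-referencing commute", {
  set.seed(16)
  rec <- eeg_recording(matrix(rnorm(4 * 5000), 4), 500, paste0("c", 1:4))
  a <- rereference_average(bandpass_filter(rec))
  b <- bandpass_filter(rereference_average(rec))
  expect_equal(a$data, b$data, tolerance = 1e-8)
})

test_that("resampling halves the count and preserves tones", {
  rec <- make_tone_rec(cbind(10, 1), dur = 30)
  rs <- resample_recording(rec, 250)
  expect_equal(ncol(rs$data), 30 * 250)
  expect_equal(rs$sfreq, 250)
  expect_equal(max(abs(mid(rs$data[1, ]))), 1, tolerance = 0.02)
  pg <- psd_periodogram(rs$data[1, 1001:3500], 250)
  expect_equal(pg$freq[which.max(pg$psd)], 10, tolerance = 0.2)
  expect_error(resample_recording(rs, 500), "below")
})

test_that("feedback epochs keep only complete LL windows", {
  ev <- rbind(
    do.call(rbind, lapply(seq(5, by = 4.5, length.out = 10), function(o)
      event_row(o, 1, "feedback", choice = "LL"))),
    do.call(rbind, lapply(seq(52, 70, by = 4.5), function(o)
      event_row(o, 1, "feedback", choice = "SS"))))
  rec <- scripted_recording(ev, dur = 75, sfreq = 250)
  es <- extract_feedback_epochs(rec)
  expect_equal(n_epochs(es), 10)
  expect_true(all(es$metadata$choice == "LL"))
  expect_equal(range(es$times), c(-1, 2 - 1 / 250))
  # an event too close to the end is dropped with a warning
  ev2 <- rbind(event_row(5, 1, "feedback"), event_row(74.5, 1, "feedback"))
  rec2 <- scripted_recording(ev2, dur = 75, sfreq = 250)
  expect_warning(es2 <- extract_feedback_epochs(rec2), "dropped")
  expect_equal(n_epochs(es2), 1)
  # no LL events at all
  rec3 <- scripted_recording(event_row(5, 1, "feedback", choice = "SS"),
                             dur = 20)
  expect_equal(n_epochs(extract_feedback_epochs(rec3)), 0)
})

test_that("delay segmentation follows the 50%-overlap window formula", {
  ev <- rbind(event_row(2, 7, "delay_start", block_delay = 7),
              event_row(12, 30, "delay_start", block_delay = 30),
              event_row(45, 1, "delay_start", block_delay = 1),
              event_row(48, 3.2, "delay_start", block_delay = 15,
                        choice = "SS"))
  rec <- scripted_recording(ev, dur = 60, sfreq = 250)
  es <- segment_delay_epochs(rec)
  counts <- table(es$metadata$block_delay)
  expect_equal(unname(counts[["7"]]), 13)
  expect_equal(unname(counts[["30"]]), 59)
  # the 1-s block contributes nothing
  expect_false("1" %in% names(counts))
  # an aborted 3.2-s wait yields floor((3.2 - 1)/0.5) + 1 = 5 windows
  expect_equal(unname(counts[["15"]]), 5)
  expect_equal(dim(es$data)[3], 250)
})

test_that("amplitude rejection uses a strict 150 uV boundary", {
  mk <- function(peaks) {
    data <- array(0, c(length(peaks), 2, 100))
    for (i in seq_along(peaks)) data[i, 1, 50] <- peaks[i]
    epoch_set("delay", data, (0:99) / 100,
              data.frame(block_delay = rep(7, length(peaks))), 100,
              c("a", "b"))
  }
  es <- mk(c(200, 100, 150, -151))
  out <- reject_epochs(es)
  expect_equal(n_epochs(out), 2)
  expect_equal(out$rejected_count, 2)
  expect_equal(out$metadata$block_delay, c(7, 7))
  # exactly-at-threshold epoch was retained
  expect_true(any(abs(out$data) == 150))
})

test_that("inclusion thresholds gate the two analyses", {
  counts <- data.frame(participant_id = c("a", "b", "c"),
                       n_feedback = c(11, 12, 40),
                       n_delay = c(0, 1, 500))
  out <- apply_inclusion_rules(counts)
  expect_equal(out$include_feedback, c(FALSE, TRUE, TRUE))
  expect_equal(out$include_alpha, c(FALSE, TRUE, TRUE))
})

test_that("epoch extraction scales linearly with the recording amplitude", {
  ev <- event_row(2, 7, "delay_start", block_delay = 7)
  set.seed(21)
  data <- matrix(rnorm(8 * 15 * 250), 8)
  rec <- scripted_recording(ev, dur = 15, sfreq = 250, data = data)
  rec2 <- rec; rec2$data <- rec$data * 3
  a <- segment_delay_epochs(rec); b <- segment_delay_epochs(rec2)
  expect_equal(b$data, a$data * 3)
})
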