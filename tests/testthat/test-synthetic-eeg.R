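test_that("background noise has the requested spectral slope", {
  fit_slope <- function(x, sfreq) {
    pg <- psd_periodogram(x, sfreq)
    sel <- pg$freq >= 1 & pg$freq <= 80
    # smooth the periodogram in octave bands before the log-log fit
    lf <- log10(pg$freq[sel]); lp <- log10(pg$psd[sel])
    bins <- cut(lf, breaks = 24)
    coef(lm(tapply(lp, bins, mean) ~ tapply(lf, bins, mean)))[2]
  }
  set.seed(2)
  white <- generate_background(1, 2^16, 250, exponent = 0, rms = 5)
  expect_lt(abs(fit_slope(white[1, ], 250)), 0.2)
  pink <- generate_background(1, 2^16, 250, exponent = 1, rms = 5)
  expect_lt(abs(fit_slope(pink[1, ], 250) - (-1)), 0.2)
  expect_equal(sd(pink[1, ]), 5, tolerance = 1e-6)
  set.seed(9); a <- generate_background(2, 1000, 250, 1, 5)
  set.seed(9); b <- generate_background(2, 1000, 250, 1, 5)
  expect_identical(a, b)
})

test_that("event tables reconstruct the session timeline", {
  cfg <- task_config()
  sess <- run_session(chooser_always_ll, cfg)
  ev <- events_from_trials(sess$trials, cfg)
  expect_true(all(diff(ev$onset) >= 0))
  fb <- ev[ev$kind == "feedback", ]
  ds <- ev[ev$kind == "delay_start", ]
  expect_equal(nrow(fb), nrow(sess$trials))
  expect_equal(nrow(ds), nrow(sess$trials))
  # LL delay periods last the full block delay; feedback follows the
  # 1-s highlight after the wait
  expect_equal(ds$duration, sess$trials$wait_elapsed)
  expect_equal(fb$onset - ds$onset, sess$trials$wait_elapsed + 1)
  # the session ends with the last score display, 1 s after its feedback
  expect_equal(max(ev$onset + ev$duration),
               cfg$demo_repeats * sum(cfg$delays) +
                 sum(sess$trials$trial_duration) - cfg$score_display_duration)
})

test_that("anticipatory alpha scales with the discounting factor and clamps", {
  gcfg <- eeg_gen_config(sfreq = 250, background_rms = 0.001)
  ev <- rbind(event_row(2, 7, "delay_start", block_delay = 7),
              event_row(10, 1, "feedback"))
  band_var <- function(rec, from, to) {
    x <- rec$data[match("POz", rec$ch_names), ]
    idx <- (round(from * 250)):(round(to * 250))
    var(x[idx])
  }
  base <- scripted_recording(ev, dur = 15, sfreq = 250)
  set.seed(3)
  hi <- inject_anticipatory_alpha(base, df = 0, gcfg)   # amplitude 4
  set.seed(3)
  lo <- inject_anticipatory_alpha(base, df = 1, gcfg)   # amplitude 1
  expect_gt(band_var(hi, 2, 9), band_var(lo, 2, 9))
  expect_equal(band_var(hi, 2, 9) / band_var(lo, 2, 9), 16, tolerance = 0.05)
  # alpha confined to the delay period
  expect_lt(band_var(hi, 10.5, 14), 1e-9)
  # zero slope removes the DF dependence entirely
  g0 <- eeg_gen_config(sfreq = 250, alpha_df_slope = 0)
  set.seed(3); a <- inject_anticipatory_alpha(base, 0, g0)
  set.seed(3); b <- inject_anticipatory_alpha(base, 1, g0)
  expect_identical(a$data, b$data)
  # amplitude clamp at zero leaves the recording untouched
  gz <- eeg_gen_config(sfreq = 250, alpha_base_amp = 2, alpha_df_slope = -2)
  expect_identical(inject_anticipatory_alpha(base, 1, gz)$data, base$data)
  # neighbor channels get the attenuated copy, frontal sites none
  expect_gt(var(hi$data[match("Pz", hi$ch_names), 500:2250]), 0)
  expect_equal(var(hi$data[match("Fz", hi$ch_names), ]), 0)
})

test_that("feedback bursts land on their clusters and windows only", {
  gcfg <- eeg_gen_config(sfreq = 250, background_rms = 0.001)
  ev <- rbind(event_row(2, 1, "feedback", choice = "LL"),
              event_row(6, 1, "feedback", choice = "SS"))
  base <- scripted_recording(ev, dur = 10, sfreq = 250)
  set.seed(4)
  out <- inject_feedback_bursts(base, gcfg)
  ch <- function(nm) out$data[match(nm, out$ch_names), ]
  # theta on the fronto-central cluster within 0.2-0.4 s of LL feedback
  theta_idx <- round((2.2 * 250):(2.4 * 250))
  expect_gt(max(abs(ch("Fz")[theta_idx])), 0)
  expect_equal(max(abs(ch("Fz")[round(3 * 250):round(5.9 * 250)])), 0)
  # delta on the centro-parietal cluster within 0.1-0.6 s
  delta_idx <- round((2.1 * 250):(2.6 * 250))
  expect_gt(max(abs(ch("Cz")[delta_idx])), 0)
  # SS feedback gets nothing by default
  expect_equal(max(abs(out$data[, round(6 * 250):round(7 * 250)])), 0)
  # POz untouched by bursts
  expect_equal(max(abs(ch("POz"))), 0)
  # zero amplitude or no feedback events: identity
  g0 <- eeg_gen_config(sfreq = 250, burst_amp = 0)
  expect_identical(inject_feedback_bursts(base, g0)$data, base$data)
  none <- scripted_recording(event_row(1, 7, "delay_start"), dur = 10)
  expect_identical(inject_feedback_bursts(none, gcfg)$data, none$data)
})

test_that("synthesized sessions are reproducible and carry artifacts on demand", {
  cfg <- task_config(delays = c(1, 7))
  sess <- run_session(chooser_alternating("LL"), cfg)
  dfv <- discount_curve(sess, cfg)$df
  g_clean <- eeg_gen_config(sfreq = 250, artifact_rate = 0)
  rec1 <- synthesize_session(sess$trials, dfv, g_clean, cfg, seed = 8)
  rec2 <- synthesize_session(sess$trials, dfv, g_clean, cfg, seed = 8)
  expect_identical(rec1$data, rec2$data)
  expect_lt(max(abs(rec1$data)), 150)
  g_dirty <- eeg_gen_config(sfreq = 250, artifact_rate = 20)
  rec3 <- synthesize_session(sess$trials, dfv, g_dirty, cfg, seed = 8)
  expect_gt(max(abs(rec3$data)), 150)
  expect_gt(length(attr(rec3, "artifact_onsets")), 0)
})

test_that("the montage must contain the analysis channels", {
  expect_error(eeg_gen_config(channels = c("Fz", "Cz", "Pz")), "POz")
})

test_that("recordings and events round-trip through EDF + sidecar", {
  cfg <- task_config(delays = c(1, 7))
  sess <- run_session(chooser_alternating("SS"), cfg)
  ev <- events_from_trials(sess$trials, cfg)
  set.seed(5)
  data <- generate_background(3, 2500, 250, 1, 20)
  rec <- eeg_recording(data, 250, c("Fz", "Cz", "POz"), ev)
  dir <- tempfile(); dir.create(dir)
  write_recording(rec, dir, "sub-001")
  back <- read_recording(dir, "sub-001")
  expect_equal(back$sfreq, 250)
  expect_equal(back$ch_names, rec$ch_names)
  expect_equal(dim(back$data), dim(rec$data))
  # 16-bit quantization bound per channel
  qstep <- 2 * max(abs(rec$data)) * 1.0001 / 65535
  expect_lt(max(abs(back$data - rec$data)), 4 * qstep)
  # events reproduce onsets exactly to one sample
  expect_true(all(abs(back$events$onset - ev$onset) < 1 / 250))
  expect_equal(back$events$kind, ev$kind)
  expect_equal(back$events$choice, ev$choice)
})
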