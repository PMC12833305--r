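next_pow2 <- function(n) 2^ceiling(log2(n))

morlet_wavelet <- function(freq, n_cycles, sfreq) {
  sigma_t <- n_cycles / (2 * pi * freq)
  half <- ceiling(5 * sigma_t * sfreq)
  t <- seq(-half, half) / sfreq
  env <- exp(-t^2 / (2 * sigma_t^2))
  # envelope normalized to sum 2 so a pure tone of amplitude a has power a^2
  w <- (2 * env / sum(env)) * exp(2i * pi * freq * t)
  w
}

#' Morlet wavelet time-frequency decomposition
#'
#' Convolves every epoch and channel with complex Morlet wavelets and
#' returns squared-magnitude power. The number of cycles grows with
#' frequency (`max(3, f/2)` by default), the usual trade-off between
#' temporal and spectral resolution. Power is normalized so a pure
#' sinusoid of amplitude a reads a^2 at its frequency.
#'
#' @param es An [epoch_set()].
#' @param freqs Frequencies of interest in Hz, within (0, Nyquist).
#' @param n_cycles Cycles per wavelet, recycled over `freqs`.
#' @return A list of class `tfr_map`: `power` (epochs x channels x freqs x
#'   times array), `freqs`, `times`, `sfreq`, `ch_names`, `metadata`,
#'   `baseline_mode` (`"none"`).
#' @export
morlet_tfr <- function(es, freqs = 1:35,
                       n_cycles = pmax(3, freqs / 2)) {
  if (any(freqs <= 0) || any(freqs >= es$sfreq / 2))
    stop("freqs must lie strictly between 0 and the Nyquist frequency")
  n_cycles <- rep_len(n_cycles, length(freqs))
  ne <- n_epochs(es); nc <- dim(es$data)[2]; ns <- dim(es$data)[3]
  longest <- ceiling(5 * (n_cycles[which.min(freqs)] /
                            (2 * pi * min(freqs))) * es$sfreq) * 2 + 1
  if (ns < longest)
    warning("epoch shorter than the longest wavelet support; ",
            "edge effects will dominate the lowest frequencies")
  power <- array(0, c(ne, nc, length(freqs), ns))
  if (ne == 0) {
    return(structure(list(power = power, freqs = freqs, times = es$times,
                          sfreq = es$sfreq, ch_names = es$ch_names,
                          metadata = es$metadata, baseline_mode = "none"),
                     class = "tfr_map"))
  }
  L <- next_pow2(ns + longest)
  # one FFT per epoch-channel, shared across frequencies; columns ordered
  # channel-fastest so the 3-d array maps straight onto the matrix
  X <- matrix(0, L, ne * nc)
  X[seq_len(ns), ] <- aperm(es$data, c(3, 2, 1))
  XF <- stats::mvfft(X)
  for (fi in seq_along(freqs)) {
    w <- morlet_wavelet(freqs[fi], n_cycles[fi], es$sfreq)
    half <- (length(w) - 1) / 2
    wpad <- complex(L)
    wpad[1:(half + 1)] <- w[(half + 1):length(w)]
    wpad[(L - half + 1):L] <- w[1:half]
    WF <- stats::fft(wpad)
    Y <- stats::mvfft(XF * WF, inverse = TRUE) / L
    P <- Mod(Y[seq_len(ns), , drop = FALSE])^2
    dim(P) <- c(ns, nc, ne)
    power[, , fi, ] <- aperm(P, c(3, 2, 1))
  }
  structure(list(power = power, freqs = freqs, times = es$times,
                 sfreq = es$sfreq, ch_names = es$ch_names,
                 metadata = es$metadata, baseline_mode = "none"),
            class = "tfr_map")
}

#' Baseline-correct a time-frequency map
#'
#' Expresses power relative to a pre-event window, per epoch, channel and
#' frequency (each epoch is corrected by its own baseline before any
#' averaging, so slow drifts between trials cancel). The default
#' `"logratio"` mode returns decibels, `10 * log10(P / mean(P_baseline))`;
#' `"percent"` returns percent signal change and `"zscore"` standardizes by
#' the baseline standard deviation.
#'
#' @param tfr A `tfr_map` from [morlet_tfr()].
#' @param window Baseline window `c(start, end)` in seconds; must lie
#'   inside the epoch and contain at least one sample.
#' @param mode `"logratio"`, `"percent"`, or `"zscore"`.
#' @return The corrected `tfr_map` (`baseline_mode` records the mode).
#' @export
baseline_correct <- function(tfr, window = c(-0.3, -0.1),
                             mode = c("logratio", "percent", "zscore")) {
  mode <- match.arg(mode)
  sel <- tfr$times >= window[1] & tfr$times <= window[2]
  if (!any(sel)) stop("baseline window contains no samples")
  # baseline statistics per epoch x channel x frequency; recycling over the
  # trailing time dimension broadcasts them across the epoch
  bm <- rowMeans(tfr$power[, , , sel, drop = FALSE], dims = 3)
  tfr$power <- switch(mode,
    logratio = 10 * log10(tfr$power / c(bm)),
    percent = (tfr$power - c(bm)) / c(bm) * 100,
    zscore = {
      bs <- apply(tfr$power[, , , sel, drop = FALSE], 1:3, stats::sd)
      (tfr$power - c(bm)) / c(pmax(bs, 1e-30))
    })
  tfr$baseline_mode <- mode
  tfr
}

#' Mean band power in a channel cluster and time window
#'
#' Averages (already baseline-corrected) power over epochs, the named
#' channels, the frequency band, and the time window — the scalar entering
#' the participant-level statistics (e.g. fronto-central theta in
#' 0.2-0.4 s, centro-parietal delta in 0.1-0.6 s).
#'
#' @param tfr A `tfr_map`.
#' @param band `c(low, high)` in Hz, inclusive.
#' @param channels Channel labels; an absent channel is an error naming it.
#' @param window `c(start, end)` in seconds, inclusive.
#' @return A single number (units follow the baseline mode).
#' @export
extract_band_window_power <- function(tfr, band, channels, window) {
  ch_idx <- match(channels, tfr$ch_names)
  if (anyNA(ch_idx))
    stop("missing channel(s): ", paste(channels[is.na(ch_idx)], collapse = ", "))
  f_idx <- which(tfr$freqs >= band[1] & tfr$freqs <= band[2])
  t_idx <- which(tfr$times >= window[1] & tfr$times <= window[2])
  if (length(f_idx) == 0) stop("band contains no frequency")
  if (length(t_idx) == 0) stop("window contains no samples")
  mean(tfr$power[, ch_idx, f_idx, t_idx])
}

#' One-sided Hann-tapered periodogram
#'
#' Power spectral density of one segment with a Hann taper and one-sided
#' density normalization (`2 |X_k|^2 / (fs * sum(w^2))`), so that summing
#' `psd * df` over frequencies recovers the signal's mean square power.
#'
#' @param x Numeric vector (one segment).
#' @param sfreq Sampling rate, Hz.
#' @return A list: `freq` (Hz, DC to Nyquist), `psd` (power per Hz).
#' @export
psd_periodogram <- function(x, sfreq) {
  n <- length(x)
  w <- hann_window(n)
  X <- stats::fft(x * w)
  n_keep <- floor(n / 2) + 1
  p <- Mod(X[seq_len(n_keep)])^2 / (sfreq * sum(w^2))
  scale2 <- rep(2, n_keep)
  scale2[1] <- 1
  if (n %% 2 == 0) scale2[n_keep] <- 1
  list(freq = (seq_len(n_keep) - 1) * sfreq / n, psd = p * scale2)
}

#' Anticipatory alpha power spectral density
#'
#' Per-participant alpha measure of the waiting period: a Hann-tapered
#' periodogram of every retained 1-s delay epoch at the requested channel,
#' averaged across epochs (given the 50%-overlap segmentation this is a
#' Welch estimate of the anticipatory spectrum), then averaged over the
#' alpha band. Averaging across epochs normalizes for the different delay
#' durations and stabilizes low trial counts.
#'
#' @param es A `"delay"` [epoch_set()].
#' @param channel Channel to read (default `"POz"`).
#' @param band Frequency band `c(low, high)` in Hz, inclusive.
#' @param by_level If `TRUE`, return one value per block delay level.
#' @return If `by_level` is `FALSE`, a scalar mean PSD (microvolt^2/Hz); if
#'   `TRUE`, a data.frame with `delay_level`, `alpha_psd`, `n_epochs`.
#' @export
compute_alpha_psd <- function(es, channel = "POz", band = c(8, 12),
                              by_level = FALSE) {
  ch <- match(channel, es$ch_names)
  if (is.na(ch)) stop("missing channel(s): ", channel)
  if (n_epochs(es) == 0) {
    if (by_level) return(data.frame(delay_level = numeric(0),
                                    alpha_psd = numeric(0),
                                    n_epochs = integer(0)))
    stop("no epochs available for PSD")
  }
  one_group <- function(idx) {
    acc <- NULL
    for (e in idx) {
      pg <- psd_periodogram(es$data[e, ch, ], es$sfreq)
      acc <- if (is.null(acc)) pg$psd else acc + pg$psd
    }
    psd <- acc / length(idx)
    freq <- psd_periodogram(es$data[idx[1], ch, ], es$sfreq)$freq
    mean(psd[freq >= band[1] & freq <= band[2]])
  }
  if (!by_level) return(one_group(seq_len(n_epochs(es))))
  levels <- sort(unique(es$metadata$block_delay))
  out <- lapply(levels, function(lv) {
    idx <- which(es$metadata$block_delay == lv)
    data.frame(delay_level = lv, alpha_psd = one_group(idx),
               n_epochs = length(idx))
  })
  do.call(rbind, out)
}
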