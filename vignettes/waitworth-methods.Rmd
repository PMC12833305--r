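---
title: "Methods: simulated experiential delay discounting with EEG"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: simulated experiential delay discounting with EEG}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(waitworth)
```

## Overview

`waitworth` rebuilds an experiential delay-discounting (DD) experiment —
behavior, EEG, and inference — as a closed simulation so that every step
of the analysis can be validated against known ground truth. The package
has three layers: a deterministic task engine with simulated choosers, a
synthetic EEG generator aligned to each simulated session, and the
measurement-plus-inference chain that turns recordings into band-power
statistics. Everything downstream of the generator is the same code a
real dataset would pass through.

## The task and its engine

Each trial offers a smaller-sooner reward (SS, starting at 16 candies)
against a constant larger-later reward (LL, 32 candies). The SS option
unlocks `ss_lockout` seconds after trial onset (1 s by default; the task
description is ambiguous between "immediately" and 1 s, and we keep the
1-s reading configurable). Choosing SS aborts the wait instantly;
refraining until the block's delay elapses makes LL available. Four
blocks run at delays of 1, 15, 30, then 7 s, each preceded by full-delay
demonstrations (`demo_repeats = 2`, one per reward option) that count
toward session duration only.

The staircase moves the SS amount down one candy after each SS choice
and up after each LL choice, clamped to [1, 30]. The step size of 1 is
the smallest unit consistent with those printed bounds ("gradually"
adjusted is all the task description fixes); it is configurable, and no
step-shrinking schedule is used.

An indifference point (IP) is the mean SS amount over three consecutive
trials with alternating choices (SS-LL-SS or LL-SS-LL). Windows overlap
by default — every consecutive alternating triplet emits an IP — because
the triplet definition does not forbid overlap; `overlap_ips = FALSE`
switches to disjoint triplets. A block terminates at six IPs, or when
six consecutive choices are made *while the offered amount sits at a
boundary* (all SS at the floor, all LL at the ceiling): the run counts
the clamped trials, not the approach to them. Trials inside an
IP-forming triplet can also count toward a boundary run. A scripted
strictly-alternating chooser therefore ends a block in exactly eight
trials with six IPs, which the tests pin down.

## From indifference points to the discounting factor

Per block, six-IP terminations score the arithmetic mean of the six IPs.
Boundary terminations carry the boundary itself: a ceiling run scores
the ceiling amount (normalizing to 1), and a floor run scores a
normalized IP of exactly 0. The floor sentinel is forced by the task's
stated extremes — a consistent SS chooser must reach a discounting
factor of 0, which `1/ss_max` normalization could never produce.

Normalization divides each block's mean IP by the **session-wide**
maximum SS amount offered. The phrase "within these blocks" could also
be read per block; we use one session-wide normalizer so the four curve
points share a scale (an agent whose SS never rose self-normalizes
to 1).

The discounting factor is the trapezoidal area under the curve
connecting normalized IPs over delay, divided by the delay span
`d_max − d_min`, so constant curves map to their constant value. The
x-axis uses raw seconds over the observed delays only — no zero-delay
anchor is interpolated, since the curve is defined as connecting the
measured points. Blocks are sorted by delay before integration
regardless of presentation order. The implementation is checked against
an independent fine-grid integration oracle to 1e-9, and obeys delay
rescaling invariance and pointwise dominance.

The 1-s block participates fully in the staircase and the DF, but never
in the anticipatory EEG analysis (only the 7/15/30-s waiting periods are
segmented).

## Simulated participants

Agents are a synthetic stand-in for human participants, not a model fit
to anyone's data. An agent discounts hyperbolically
(`V = A / (1 + kD)`; exponential is available), chooses LL with
probability `logistic(beta * (V_LL − V_SS))`, and — having committed to
waiting — aborts with a memoryless per-second hazard, converting the
trial to an SS choice at the abort time. The agent evaluates LL at the
block's full delay rather than the remaining time, matching how choices
are framed per delay; the whole-second hazard is the simplest process
that produces mid-delay aborts.

The default cohort sampler draws `k ~ LogNormal(log 0.01, 1)` per
second, fixes `beta = 2` per candy, and sets
`abort_hazard = min(0.05, k/2)`. The log-normal concentrates mass at
small k, so most agents are patient and the cohort's DF distribution is
negatively skewed with a ceiling near 1 — the regime this kind of task
pushes instructed participants into (mean DF ≈ 0.82 under the default
seed-independent conditions). The hazard scaling is a one-time
calibration of the simulator to that regime, documented as such and not
revisited; it also yields the expected positive Spearman association
between DF and session duration, since waiting for LL takes longer.

## Synthetic EEG

The generator emulates exactly the statistical structure the analysis
assumes, and nothing more:

* **Background**: per-channel 1/f noise (exponent 1, RMS 10 µV),
  synthesized by spectral shaping of white noise.
* **Anticipatory alpha**: a 10 Hz sinusoid during each waited delay
  period of the 7/15/30-s blocks, amplitude
  `max(0, alpha_base_amp + alpha_df_slope * DF)` (defaults 4 and
  −3 µV/DF, so more impulsive agents carry more anticipatory alpha). The
  phase is drawn independently per delay period because anticipatory
  alpha is non-phase-locked power. The spatial profile is schematic:
  full amplitude at POz, half at Pz and Oz, zero elsewhere — the
  analysis reads only POz and the neighbors add realism.
* **Feedback bursts**: Hann-windowed 6 Hz theta over Fz/FC1/FC2 at
  0.2–0.4 s and 2 Hz delta over Cz/CPz at 0.1–0.6 s after each LL
  feedback cue (SS feedback is excluded from the analysis and carries no
  burst by default).
* **Artifacts**: 400 µV square pulses at a Poisson rate on random
  channels, guaranteeing the ±150 µV rejection path has work to do.

The montage defaults to the eight channels the analysis names (Fz, FC1,
FC2, Cz, CPz, Pz, POz, Oz) at 500 Hz. Recordings are written as EDF
(16-bit, 1-s records; the true sample count rides in the header's
reserved field) with a BIDS-style `events.tsv` sidecar; the writer and
reader are part of the package and round-trip to within 16-bit
quantization. What the generator does **not** emulate: volume
conduction, realistic artifact morphology, non-stationary background,
inter-channel correlation beyond the injected sources. Passing recovery
tests therefore demonstrates the pipeline's correctness, not the
physiological fidelity of the signals.

## Preprocessing

The chain is band-pass filter → average re-reference → (optional
external cleaning callback) → resample → epoch → amplitude rejection.
Component-based artifact removal is inherently manual and is not
implemented; the callback slot is where such a cleaner would go.
Because epoch windows are expressed in seconds, epoching after
resampling is observationally equivalent to the reverse order.

The band-pass is a zero-phase Butterworth cascade (high-pass order 2 at
0.1 Hz, low-pass order 6 at 40 Hz). The default implementation applies
the squared Butterworth magnitude spectrally — exactly the response of
running the IIR filters forward and backward — after 10 s of reflection
padding; a `filtfilt` time-domain implementation is kept and the two are
cross-checked on tones in the tests. At 10 Hz the response is flat to
well under 1 dB; at 50 Hz attenuation exceeds 20 dB; DC is removed.
Resampling to 250 Hz is Fourier-domain (spectrum truncation), which
preserves in-band amplitude and frequency exactly for band-limited
signals; a polyphase alternative was rejected after showing ~2.5%
passband ripple.

Feedback epochs span [−1, 2] s around the feedback cue, LL trials only;
incomplete windows are dropped with a warning. Waiting periods use the
**actually waited** interval (aborted waits contribute fewer windows),
cut into 1-s windows every 0.5 s: a wait of length T yields
`floor((T−1)/0.5) + 1` windows — 13 for a full 7-s wait, 59 for 30 s.
Windows are half-open in samples so counts are exact. Rejection drops
any epoch whose peak absolute amplitude on any channel strictly exceeds
150 µV ("exceeding" reads as strict; exactly 150 is retained).
Participants need ≥ 12 retained feedback epochs for the theta/delta
analysis and ≥ 1 retained delay epoch for the alpha analysis.

## Spectral measurement

Morlet wavelets cover 1–35 Hz with `n_cycles = max(3, f/2)`, the
standard resolution trade-off (nothing in the task fixes it). Power is
normalized so a pure tone of amplitude a reads a²; epochs shorter than
the longest wavelet support trigger a warning rather than an error,
since the lowest frequencies of a 3-s epoch are inevitably edge-affected.
Baseline correction is per epoch (each epoch's own −300…−100 ms mean,
per channel and frequency) in `logratio` (dB) mode by default, with
percent and z-score alternatives; corrected values are averaged, not the
other way around. Feedback measures are means over epochs × cluster ×
band × window: theta 4–7 Hz at Fz/FC1/FC2 in 200–400 ms, delta 1–3 Hz at
Cz/CPz in 100–600 ms. The delta cluster follows the methods definition
(Cz, CPz); where a CPz/Pz variant is wanted it is a one-argument change.

Anticipatory alpha PSD is a Hann-tapered one-sided periodogram
(µV²/Hz) of every retained 1-s delay epoch at POz, averaged across
epochs — a Welch estimate, given the 50% overlap segmentation — then
averaged over 8–12 Hz. Averaging across however many epochs a
participant has normalizes for unequal delay durations; the estimator is
unbiased in the epoch count, which the tests verify by subsampling, and
it reproduces the analytic sinusoid power a²/2 within 10%.

## Inference

Outliers beyond ±3 SD of each measure's mean (single pass, strict
inequality) are removed before modeling. "GLM" is implemented as
Gaussian-identity — equivalent to OLS, matching F-statistic reporting —
with the family configurable; the DF term is tested on (1, n−2) df and
checked against a normal-equations oracle. The alpha model is
`alpha_psd ~ delay_level × DF + (1 | participant)`, REML, sum-to-zero
contrasts for the delay factor, Type-III F tests with Satterthwaite
denominator df (the conventional route to fractional df reporting; the
method itself is not fixed by the study design). Under sum contrasts the
`df` coefficient is the DF slope at the average delay level, which is
what the sign-recovery experiment inspects. Significant delay effects
trigger Benjamini–Hochberg-adjusted pairwise post-hocs; significant
interactions trigger per-level simple slopes via estimated marginal
trends.

## Recovery experiments and problem sizes

Three experiments close the loop between generators and analysis:

* **Alpha sign recovery** (`run_alpha_sign_recovery`): 52 simulated
  participants through the *full* pipeline — behavior, EEG synthesis at
  500 Hz, preprocessing, segmentation, rejection, PSD, mixed model. With
  the default negative DF→alpha slope the model recovers a negative,
  strongly significant DF effect; delay and interaction terms, which
  carry no injected effect, stay null.
* **GLM null calibration** (`run_glm_null_calibration`): 800 repetitions
  at reduced scale (12 participants per repetition, 6 feedback epochs
  each, Morlet grid restricted to 1–8 Hz, which covers both analysis
  bands and the baseline). Bursts are injected at constant amplitude —
  independent of DF by construction — and the measured theta/delta
  scalars are modeled on DF; the rejection rate at α = 0.05 should match
  the nominal level. The reduced scale is the package's own design
  choice: calibration concerns the test's level, which does not depend
  on per-repetition cohort size, while 800 repetitions keep the binomial
  uncertainty of the estimated rate below one percentage point.
* **Behavioral sign** (`run_behavioral_sign`): a 54-agent cohort under
  the default sampler, checking negative DF skewness and the positive
  DF–duration Spearman correlation.

`recovery_experiment()` bundles all three; every stochastic entry point
takes an explicit seed and derives per-participant sub-seeds from it, so
reruns are bit-identical.

## Numerical choices and degenerate inputs

* Strict boundaries everywhere they matter: rejection (> 150 µV),
  outlier trimming (> 3 SD), inclusion (≥ 12, ≥ 1).
* FFT work is done at 2–3–5-smooth lengths (pad or truncate as
  appropriate) to avoid pathological mixed-radix sizes on arbitrary
  session durations.
* `compute_df` requires at least two distinct delays; constant DF or
  duration vectors make the Spearman correlation undefined and are
  flagged with a warning rather than an error.
* Zero-epoch sets propagate as empty results (alpha rows are simply
  absent for a participant with nothing retained); the mixed model
  refuses fewer than two participants, and the pipeline skips the LMM
  when the fixed effects would exhaust the observations.
* EDF scaling re-reads its own printed 6-significant-digit physical
  range so writer and reader agree exactly.

## Known limitations

The agents have no learning, no quasi-hyperbolic (β–δ) structure, and no
session-level fatigue; the EEG generator's scalp topography and
amplitude scale are placeholders for recovery testing, not estimates of
any real effect size; component-based artifact removal is out of scope;
and all calibrations (sampler, amplitudes) describe the simulator, not
people. Conclusions supported by the test suite are therefore about the
correctness and calibration of the measurement-and-inference chain.
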