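Package: waitworth
Title: Simulation and Analysis of Experiential Delay-Discounting EEG Experiments
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Tools to simulate and analyse an experiential delay-discounting
    experiment with concurrent EEG. Provides a deterministic staircase task
    engine with indifference-point detection and an area-under-the-curve
    discounting factor, simulated hyperbolic/exponential discounting agents
    with softmax choice noise, a synthetic multichannel EEG generator with
    1/f background, anticipatory parieto-occipital alpha tied to the
    discounting factor and feedback-locked theta/delta bursts, a
    deterministic preprocessing chain (band-pass filtering, average
    re-reference, resampling, epoching, amplitude rejection), Morlet
    time-frequency decomposition and Welch-style alpha power spectral
    density, and the inferential layer (Gaussian GLMs, linear mixed models
    with random participant intercepts, FDR post-hocs, simple slopes)
    together with end-to-end parameter-recovery experiments.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    signal,
    lme4,
    lmerTest,
    emmeans,
    e1071,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
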