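Package: cardioresp
Title: Cardiorespiratory Modulation of Reaction Times in Delayed
    Matching-to-Sample Tasks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and analysis of how respiratory phase transitions and
    R-R interval (RRI) velocity modulate reaction times in a delayed
    matching-to-sample task. Provides a synthetic-data generator with known
    ground truth (respiratory flow with gamma-distributed cycle periods,
    heartbeats via integral-pulse-frequency-modulation with respiratory sinus
    arrhythmia, and task event streams with injectable reaction-time effects),
    signal processing (baseline subtraction, flow zero-crossing transition
    detection with a +/- 2 SD excursion rule, zero-phase 0.5-40 Hz ECG
    band-pass, Pan-Tompkins-style R-wave detection), trial-level classification
    (respiratory-phase conditions, half-of-trial transition labels, RRI
    velocity and its per-subject binning, robust z standardization of reaction
    times), the group-level statistical battery (Friedman with Wilcoxon post
    hocs, repeated-measures ANOVA with Greenhouse-Geisser correction, two-way
    ANOVA, Kruskal-Wallis), and random-intercept multilevel models of windowed
    reaction time on transition occurrence rates, RRI velocity, and accuracy.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    signal,
    lme4,
    lmerTest,
    jsonlite,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
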