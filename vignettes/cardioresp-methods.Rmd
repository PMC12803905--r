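---
title: "Cardiorespiratory modulation of reaction times: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Cardiorespiratory modulation of reaction times: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cardioresp)
```

## The scientific problem

During a delayed matching-to-sample (DMTS) task, reaction times (RTs) on
individual test trials fluctuate with the state of the cardiorespiratory
system. Two phenomena are of interest:

1. **Respiratory phase transitions.** The onset of inhalation — the
   exhalation-to-inhalation (EI) transition — falling inside the
   cue-to-button-press window prolongs the RT, most strongly when it falls in
   the *second half* of the window. The inhalation-to-exhalation (IE)
   transition has a much weaker effect.
2. **RRI velocity.** The R-R interval (RRI) of the ECG lengthens during
   exhalation and shortens during inhalation (respiratory sinus arrhythmia,
   RSA). The *velocity* of this change across a trial,
   $\Delta RRI = RRI(\text{press}) - RRI(\text{cue})$, correlates positively
   with RT: trials on which the heart is decelerating are slower.

The package reimplements the full analysis chain for this question — signal
processing, trial classification, the group-level test battery, and
random-intercept multilevel models — together with a synthetic-data generator
that produces cohorts with known ground truth, so that every stage is
testable without access to human recordings.

## The synthetic cohort generator

`generator_config()` fixes the study conditions: 36 subjects, 30 blocks of
4 sample cues, a uniform 10–13 s delay and 3 test cues (90 test trials,
45 match / 45 nonmatch, stimuli drawn from the $6^4 = 1296$ image space);
respiration at 0.278 Hz with cycle-period CV 26.8 %; mean RRI 0.85 s.

**Respiration.** Cycle periods are i.i.d. gamma distributed with the target
mean and CV. The gamma family was chosen for its strictly positive support
and because mean and CV pin down both parameters; only those two moments are
specified by the study conditions. A fixed fraction (0.4) of each cycle is
inhalation. Rendered flow is a half-sine per phase, inhalation-positive
(the sign convention is recorded in the trace metadata so detection is
convention-agnostic), so noise-free flow crosses zero exactly at each
transition.

**Heartbeats.** The instantaneous target RRI is
$r(t) = \bar r \mp a$ (minus during inhalation, plus during exhalation, with
a 0.3 s linear ramp after each transition, $a = 0.05$ s). Beat times come
from integral pulse frequency modulation (IPFM): a beat is emitted whenever
$\int 1/r(t)\,dt$ crosses an integer. The rate function is deterministic
given the respiratory phase — there is no beat-to-beat variability beyond
RSA. That is a deliberate simplification: it makes ground-truth $\Delta RRI$
exactly recoverable, at the cost of overstating how phase-locked real RRI
series are. Consequences for what the tests show are discussed below.

**Reaction times and injected effects.** Base RTs are lognormal (median
1.1 s, shape 0.25). Two effects are injected additively:

* `beta_eit2nd_s` (0.35 s) is added when an EI transition falls in the second
  half of the trial. The label depends on the final RT while the injection
  changes the RT, a circularity resolved by a single adjustment pass: the
  provisional label is computed under the base RT, the prolongation applied,
  and the *final* label recomputed from the final press time and recorded as
  ground truth. A small fraction of trials therefore end up labelled EIt-2nd
  without having received the boost (or vice versa), which is realistic —
  the observable label is the final one.
* `beta_drri` (1.2 s/s) times the realized $\Delta RRI$ at the adjusted
  press time.

The two defaults were calibrated jointly, since the effects compete through
the RSA physiology: EIt trials mechanically carry negative $\Delta RRI$
(inhalation onset means the RRI is about to shorten) and IEt-1st trials
positive $\Delta RRI$. The chosen pair reproduces the qualitative orderings
of the findings — EIt-2nd the largest half-condition robust-z RT, the high
positive $\Delta RRI$ bin the largest bin mean, and high positive
$\Delta RRI$ more frequent in IEt than EIt conditions — in essentially every
36-subject cohort.

**Accuracy.** Correct responses are Bernoulli with base probability 0.91 and
a 0.05 decrement on EI-transition trials (overall accuracy ≈ 90 %). A
block-level attentional state (SD 0.08 log-units on RTs, 0.07 accuracy
decrement per state SD) couples slow blocks to error-prone blocks. This
state is needed to reproduce the negative window-level accuracy–RT
association of the multilevel models: a purely trial-level lapse mechanism
does the opposite, because slow error trials are censored from the
correct-trial RT mean, and the surviving correct trials in low-accuracy
windows are then *fast*.

Unspecified protocol timings (1 s sample cues with 1 s gaps, 2 s
inter-trial gap, 5 s inter-block interval) are configurable defaults
recorded in the output metadata.

## Signal processing

* **Baseline and noise.** Flow is baseline-subtracted
  (`subtract_baseline()`); the baseline noise SD can be estimated from a
  pre-task quiet window (`estimate_noise_sd()`). The transition rule's
  "± 2 SD" is interpreted as 2 SDs of this baseline noise, since the rule
  exists to ensure crossings exceed the noise floor.
* **Transitions.** `detect_respiratory_transitions()` finds zero crossings
  whose subsequent excursion exceeds $2\sigma$ before re-crossing zero
  (hysteresis); upward crossings are EI, downward IE under the declared sign
  convention. Two numerical choices: (i) under broadband noise the crossing
  is localized on a zero-phase low-passed copy (default 5 Hz, an order of
  magnitude above the respiratory band) — raw 1 kHz samples chatter around
  slow crossings and would scatter the onset by tens of milliseconds;
  with zero noise the raw trace is used and crossings are exact.
  (ii) alternation is enforced by dropping the later of two same-type
  onsets (a 0.5 s same-type debounce window is the configurable minimum),
  so the output always strictly alternates.
* **ECG.** A zero-phase 0.5–40 Hz band-pass (high-pass/low-pass Butterworth
  cascade; zero-phase so R-wave times are not shifted), then Pan-Tompkins
  style R-wave detection: differentiate, square, 150 ms moving-window
  integration, adaptive signal/noise threshold with a 200 ms refractory
  period, and refinement of each beat to the local ECG maximum. Manual beat
  verification is replaced by a QC rule flagging RRIs more than 3
  subject-SDs from the subject mean (`qc_rri_outliers()`).
* **RRI series.** $RRI_n = R_n - R_{n-1}$, and interval $n$ owns the
  half-open range $(R_{n-1}, R_n]$: an event coincident with an R wave
  belongs to the interval that R wave terminates. The boundary convention
  is arbitrary but fixed and tested.

## Trial classification

Transitions strictly inside the *open* interval (cue, press) determine the
condition: none → INH or EXH by the phase at cue (pooled as "NOt"); exactly
one type → EIt or IEt; both → DOUBLE. A transition exactly at cue or press
is excluded by the open interval; the half label uses the *first* transition
of each type, with a midpoint transition assigned to the second half. Both
conventions are unobservable edge cases in continuous time; they are fixed
here and exercised by tests.

$\Delta RRI$ is the RRI covering the press minus the RRI covering the cue
(zero when both fall in one interval); the supplementary variant
$\Delta RRI_b$ replaces the cue RRI with the last RRI ending at or before
the cue. Per subject and per sign, trials are binned by the ratio
$r = |\Delta RRI| / \max |\Delta RRI|$ of that sign: $r \ge c$ is the high
bin. The default boundary $c = 0.5 = 10^{\log_{10} 0.5}$ follows the
log-space boundary printed with the bin definitions; the accompanying
"30–100 %" gloss would instead give $c \approx 0.316$ (the log-midpoint of
$[-1, 0]$), a discrepancy in the source left unresolved — $c$ is a config
knob, the formulaic boundary is the default, and exact zeros go to the low
positive bin. The maximum is taken over all trials with a valid
$\Delta RRI$ (correct and incorrect), binning being a physiological, not
behavioral, partition.

Robust-z RTs are $(RT - \text{median}) / IQR$ with median and IQR over the
subject's *correct* trials (the analyses concern correct-trial RT; whether
the scale should include error trials is unstated in the source — correct
only is implemented). By construction the correct-trial z has median 0 and
IQR exactly 1; subjects with zero IQR or fewer than four distinct correct
RTs are flagged and excluded.

## Group-level statistics

For each subjects × conditions matrix the branch is chosen the way the
original analyses branch: Shapiro-Wilk per condition at α = 0.05 decides
parametric versus nonparametric; Mauchly's test decides whether the
Greenhouse-Geisser epsilon (computed from the double-centered covariance)
deflates the repeated-measures F's degrees of freedom. The nonparametric
branch is Friedman's test with all-pairwise Wilcoxon signed-rank post hocs,
Bonferroni factor $k(k-1)/2$ (the family is taken to be all pairwise
comparisons within one omnibus; the family size is not stated in the
source). First-test-trial restrictions are analyzed at the trial level with
Kruskal-Wallis and pairwise rank-sum tests, mirroring the printed test
names; the unit of analysis there is ambiguous in the source and flagged as
such. DOUBLE trials are analyzed at the trial level with a 2 × 2 two-way
ANOVA (IEt half × EIt half) and pooled-SD t post hocs.

The frequency analyses compute, per subject, the rate of high-positive
$\Delta RRI$ trials within each half condition, and the rate of EIt-2nd
trials within each $\Delta RRI$ bin, each analyzed by the repeated-measures
branch. Under the default RSA physiology the high-positive rate is larger
in IEt conditions and the EIt-2nd rate peaks in the high-negative bin —
the temporal-mismatch signature.

## The multilevel models

Trials are aggregated over two-block windows (15 windows of 6 tests): mean
correct-trial RT (windows with no correct trial are dropped, not imputed),
accuracy over all trials, EIt-2nd and IEt-2nd occurrence rates over all
trials (transition occurrence is independent of correctness, so all trials
count), and mean $\Delta RRI$. Every variable is z-scored over all
subject-windows; predictors are then centered on each subject's mean. The
response is *not* subject-centered: the model equations center only the
predictors and house subject means in a random intercept, and
subject-centering the response would make that intercept degenerate. (The
prose description of the original centering is ambiguous on this point; the
equations are taken as authoritative, and `subject_center_rt = TRUE` exposes
the alternative.)

Model 1 is
$$RT_{ij} = \beta_{0j} + b_1\,\widetilde{EIt2nd}_{ij} + b_2\,\widetilde{\Delta RRI}_{ij} + b_3\,\widetilde{Acc}_{ij} + r_{ij},\qquad \beta_{0j} \sim N(\beta_{00}, u^2),$$
with fixed slopes and a Gaussian random intercept per subject; Model 2
replaces the EIt-2nd rate with the IEt-2nd rate. Estimation is REML with
Satterthwaite degrees of freedom via lmerTest — the package named by the
source, at its default settings. `fit_random_intercept()` returns a classed
fit with `print`, `summary`, `coef`, `predict`, `fitted`, `residuals`
methods.

`simulate_model_cohort()` generates cohorts directly on the normalized
aggregate scale for parameter-recovery and type-I-error studies (truth on
that scale only exists after aggregation); its default noise magnitudes
(residual SD 0.78, intercept SD 0.5) put coefficient standard errors in the
few-hundredths range typical of a 36 × 15 design.

## Problem sizes, tolerances and degenerate inputs

The shipped tests run detection on full-length rendered recordings of all
36 subjects at 20 dB (flow) and 10 dB (ECG) SNR; oracle-equivalence checks
on 10^4 randomized instances per operation; 100 aggregate-scale cohorts for
parameter recovery plus 200 for the null; and 100 event-level 36-subject
cohorts for the qualitative orderings. Numerical tolerances: transitions
matched within ±30 ms under noise and ±1 sample noise-free; R waves within
±5 ms noise-free; robust-z invariants exact.

Degenerate inputs are contracts, not crashes: an all-zero or sub-threshold
flow trace yields an empty phase series with a warning; a flat ECG an empty
beat list; all-zero $\Delta RRI$s a low-positive subject with a QC warning;
cohorts too small for a repeated-measures test mark that analysis skipped;
windows without correct trials are dropped with a message.

## What passing tests do and do not show

The generator emulates the study conditions but idealizes real data in
known ways: no beat-to-beat HRV noise beyond RSA, no sighs or breathing
irregularities beyond gamma cycle variation, stationary RSA amplitude, no
electrode artifacts, and injected RT effects that are exactly additive.
One visible consequence: because RSA is deterministic given phase, the
window-mean $\Delta RRI$ is nearly collinear with the transition-occurrence
rates, so Model 2's $\Delta RRI$ coefficient — which in real data retains a
positive effect from HRV variation independent of IEt timing — is
sign-unstable on synthetic cohorts and is not asserted by any test.
Passing detection tests therefore demonstrate correctness of the
implementations under the stated noise models, not field performance on
clinical recordings; the multilevel-model recovery results demonstrate that
the estimation machinery is unbiased and calibrated on data generated by
the model it assumes, which is the appropriate test of the machinery, not
evidence about any particular human dataset.
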