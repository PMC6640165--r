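---
title: "Methods: simulating and analysing a positive-activity intervention study"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: simulating and analysing a positive-activity intervention study}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(affectpipe)
```

## The design being modelled

`affectpipe` implements the full measurement and analysis chain of a
randomized pre/post writing-intervention study in which participants are
assigned to a positive (prosocial) or negative ("antisocial") writing
condition, and the intervention's effect is sought in three measurement
families:

* **self-report**: 14 well-being measures (affect, gratitude, elevation,
  optimism, self-esteem subscales, psychological needs, meaning in life)
  administered before and after the writing task;
* **cognitive tasks**: recognition memory for valenced words (signal
  detection theory), construal of positive/negative/ambiguous situations,
  and a timed word-find attention task — 18 outcome measures;
* **physiology**: 12-channel EEG at 128 Hz with a photodiode sync channel,
  and a wristband providing interpolated RR intervals (4 Hz), tonic/phasic
  skin conductance (20 Hz) and skin temperature.

Because the raw data of such studies are typically unavailable, the package
is built around a synthetic-cohort generator with *known ground truth*:
every downstream stage (scoring, signal processing, statistics,
classification) can be validated against what the generator injected.

## The synthetic generator and its defaults

`sim_config()` fixes the study conditions. The defaults are not free dials;
they encode a specific emulated design and are held fixed:

* **n = 245** participants, randomized roughly 1:1 to the two arms.
* **Per-arm standardized mean changes** for the 14 self-report measures
  (`default_self_report_effects()`), expressed in pre-test SD units. Five
  measures carry reliable between-arm differences (elevation +0.188,
  gratitude +0.199, positive affect +0.260 favouring the positive arm;
  negative affect −0.153 and negative social emotions −0.273); the rest are
  near-null.
* **Inter-measure correlation**: exchangeable |r| = 0.3, negative between
  the two negatively keyed measures (negative affect, negative social
  emotions) and the positively keyed ones. Published panels of this kind
  show substantial collinearity among positive-affect-adjacent measures but
  rarely print the full correlation matrix, so a single exchangeable
  parameter is used; it is fully configurable, and the sign-flipped
  exchangeable form is positive definite for any |r| < 1.
* **Change noise** `change_sd = 0.45` (pre-test SD units). This corresponds
  to a test–retest reliability of about 0.9 over the roughly 40-minute
  pre–post interval, a typical value for state measures over short
  intervals. Raw-score variances are not published for the emulated design,
  so this is a modelling choice, stated once and not tuned.
* **Cognitive tasks**: per-valence hit probability 0.70 and false-alarm
  probability 0.20 (moderate recognition performance), construal ratings
  driven by a latent image-valence signal of ±0.6 on the normalized scale,
  word-find discoveries with exponential gaps of mean 35 s (about six
  minutes for nine words). Condition effects on cognition default to
  **zero**, matching the emulated finding of null cognitive effects;
  `cognitive_effects` can inject them for power studies.
* **EEG**: 1/f background (exponent 1, 8 µV RMS), 10 Hz alpha of 10 ± 2 µV
  (posterior-dominant), eyeblinks as 100 µV / 400 ms raised cosines on
  frontal channels at 0.2 Hz, and artifact bursts of 600 µV / 1 s. The
  blink and artifact amplitudes are deliberately placed on opposite sides
  of the 400 µV rejection threshold so that ground-truth recovery is
  unambiguous.
* **Wristband**: baseline RR 800 ms with sinusoidal low-frequency (0.1 Hz)
  and high-frequency (0.25 Hz, respiratory) modulations of 20 ms depth,
  beat-to-beat noise 5 ms; Poisson skin-conductance responses on a slow
  tonic drift; temperature as a bounded random walk.

Event timelines follow the word-presentation design: 1 s stimuli with a
uniformly jittered 2.75–3.25 s inter-stimulus interval.

### What the generator does *not* emulate

Real EEG nonstationarity, volume-conducted source topographies beyond the
frontal blink field, ectopic beats or RR artifacts, electrodermal
habituation, and any coupling between self-report change and physiology.
Passing tests therefore demonstrate that the *pipeline* is correct and
calibrated, not that real recordings of this design would yield the same
effect sizes.

## Cognitive scoring

Recognition memory uses the probit-based signal-detection measures
d′ = z(H) − z(F) and C = −(z(H) + z(F))/2, per word valence. Boundary
rates (0 or 1) make the probit infinite; the default correction replaces
them with 1/(2N) and 1 − 1/(2N) (N = 16 words per cell). A literal
alternative — pinning d′ itself to 1/(2N) or 1 − 1/(2N) — is selectable
(`correction = "dprime"`), but the corrected-rate reading is the default
because pinning d′ to 1/(2N) for a perfect hit rate would *penalize*
perfect performance, which the paired rule for rate = 1 contradicts.
Positive C is reported as a conservative ("new") bias; the field uses both
conventions and the choice is stated here once.

Construal ratings map linearly from 1–7 onto (−1, +1) with
negative-polarity items sign-flipped, then average within image valence;
the scorer treats items generically by polarity, so duplicated item text in
a stimulus file is a stimulus issue, not a scoring rule. Word-find returns
the mean find order and mean find time per valence. Scoring requires all
nine words in strict mode; since no partial-completion rule is published
for such designs, a lenient mode (NaN for affected groups, flagged) is
provided without claiming fidelity.

## EEG pipeline

Preprocessing applies, in order: zero-phase Butterworth conditioning
(0.1 Hz high-pass, 60 Hz low-pass, applied forward–backward), bad-channel
removal (minimum four good channels), average re-referencing, and
automatic eyeblink removal. No filter family is canonical for this step;
4th-order Butterworth zero-phase is the common default and is used
everywhere. Blink removal uses an SVD spatial decomposition: a component
is flagged when frontal channels carry > 50% of its squared spatial
loading and > 60% of its time-course power lies below 4 Hz; the flagged
component is subtracted and the data re-referenced again. The criterion
values and the removal decision are logged.

Artifact rejection marks 0.3 s sliding windows per channel when (1) the
absolute amplitude exceeds 400 µV, (2) the window peak-to-peak exceeds
400 µV, or (3) the Hilbert envelope of any band-filtered copy (delta 1–4,
theta 4–7, alpha 8–15, beta 16–31 Hz) exceeds 40 µV. Rules 1–2 apply to
the conditioned channel and rule 3 to the band envelopes, as the procedure
is conventionally written. Event windows with more than 50% masked samples
are dropped; published procedures rarely state how masks interact with
event windows, so this threshold is a documented package choice.

Per event window and channel the six scalar features are theta/alpha/beta
band RMS, the prefix rescaled-range Hurst exponent, the Petrosian fractal
dimension, and the Higuchi fractal dimension (the third complexity scalar
of the classic EEG feature toolbox trio). One-second windows make the
Hurst estimator noisy; it is a relative feature, not a physical estimate.
Features are averaged over events and channels within four groups
(F = F7/F8/Fz, C = Cz/C3/C4, P = P3/P4/P7/P8/Pz, O = Oz), giving
6 × 4 = 24 variables, reduced to five principal components. Alpha
asymmetry (right minus left alpha RMS for F7–F8, P3–P4, P7–P8) is kept out
of the PCA and analysed separately, reflecting its prior theoretical
status. The montage and pairs are configuration-driven because commercial
montages vary; the default 12-channel montage is the set consistent with
the channel groups. PCA is fitted *across* participants on the per-task
feature table (the within-subject alternative of fitting five components
per subject is statistically ill-posed at one row per subject and is not
implemented).

## Autonomic pipeline

RR intervals are interpolated with a natural cubic spline onto a 4 Hz grid
(no extrapolation). Spectral estimation uses a Hann-windowed averaged
periodogram (Welch) with 50% overlap and linear detrending, normalized so
a sinusoid of amplitude A integrates to A²/2; HF = 0.15–0.4 Hz,
LF = 0.04–0.15 Hz. Stimulus-on windows of ~1 s are far shorter than one
LF cycle (25 s), so band powers cannot be estimated within the event
window itself: the package computes a sliding-window band-power *feature
signal* (default 64 s windows) and samples it at the event times. This is
a necessary and deliberately prominent deviation from any within-event
spectral reading of the procedure. Mean amplitude is the within-window
mean of each feature signal and peak-to-peak its within-window range,
averaged over the task's events. When only raw conductance is available, a
stand-in tonic/phasic split is used (running-median baseline as tonic,
residual as phasic; the two reconstruct the input exactly); device-supplied
decompositions pass through untouched.

## Change statistics

Measures are z-scored with mean and SD pooled over all participants and
both sessions (the normalizing statistics are not published for such
designs; pooling is the symmetric choice), and the change is
z(post) − z(pre). Pooling slightly shrinks observed standardized changes —
by the factor sqrt(1 + change_sd²/2) ≈ 1.05 at the default noise — which
the calibration tests account for by comparing at simulation precision.
Each measure's change is regressed on an intercept and the dummy-coded
condition (positive = 1): the intercept estimates the negative arm's mean
change and the coefficient the between-arm difference. (A verbal reading
that the intercept indicates change "in the positive condition" conflicts
with this model; the model as written wins.) Family-wise control is
Bonferroni per variable group: α = 0.05/18 ≈ 0.0028 for the cognitive
family and 0.05/14 ≈ 0.0036 for self-report; physiological families are
sized by their emitted variable counts at run time. Concurrent-validity
models regress each self-report change on a full feature set via OLS with
an overall F test at the family-corrected α.

## Classification

`nested_cv_classify()` implements the six-step scheme exactly: stratified
80/20 outer split; the training set split into three stratified thirds;
for each regularization value, training on two thirds and validating on
the third, rotated so each third validates once; the best mean validation
accuracy selects the value (ties resolved toward the most regularized
model); the selected model is refit on the full training set and scored on
the held-out test set; the whole procedure repeats 20 times and the mean ±
SE of training and test accuracy is reported. Outer and inner splits are
stratified by condition — with ~49 test observations an unstratified split
can lose a class entirely.

Four model families are available. L1-regularized logistic regression
(glmnet) searches λ ∈ {10⁻³, …, 10, 0}, the 0 entry meaning an
unregularized fit (linear models only). A literal L1-penalized hinge SVM
is not available in the installed stack; the linear-kernel SVM searches
its native cost parameter over the analogous inverse grid, AdaBoost-SVM is
a weighted-resampling AdaBoost over linear SVMs, and random forests search
minimum node size — each family's own complexity control over a comparable
grid, preserving the intent (complexity limited, searched by inner
validation) where a literal L1 penalty does not exist.

`hierarchical_evaluation()` reduces each feature group to five principal
components and evaluates each group alone plus the baseline (self-report)
group with each addition. By default the reductions are fitted inside each
training split (leak-free); `pca_scope = "global"` reproduces the simpler
fit-once-on-everything variant some published procedures imply. A sparsity
note: with L1 logistic, variables uninformative about condition are driven
to exactly zero, so the best-run coefficient vector doubles as a variable
selection readout.

## Numerical choices and degenerate inputs

* Probit transforms use `qnorm`; corrected rates keep d′ finite at
  boundary performance.
* `filtfilt` is used for every filter: zero phase, so event-locked
  features are not time-shifted.
* The analytic-signal envelope is computed by FFT; for a pure in-band
  sinusoid it equals the amplitude away from the edges, which anchors the
  40 µV envelope rule tests.
* Constant channels yield an all-false artifact mask (band-filtering
  removes DC) unless the DC itself exceeds the 400 µV rule.
* Zero-variance feature columns are dropped (warning) before PCA; rank
  deficits return fewer components with a warning.
* Degenerate CV splits (a class missing) are re-drawn a bounded number of
  times, then error.
* All generators derive per-participant, per-session RNG streams from the
  single study seed, so every output is bit-reproducible.

## Problem sizes used in tests

The packaged tests exercise the study-scale cohort analyses at their
natural sizes (n = 245 cohorts, 1000-replicate type-I calibration, 100
replicate sign-recovery runs) and the raw-signal paths at reduced sizes
chosen for tight feedback (40–60 s recordings, 6–48 events, cohorts of
4–40 for signal round trips). The end-to-end alpha-shift recovery test
uses 40 participants × 2 sessions of 45 s EEG, which is ample to detect a
1-SD injected shift; these sizes are stated here as package choices so the
suite remains fast and deterministic.

## Known limitations

* The generator's effect structure is additive and Gaussian; real panels
  have floors/ceilings and item-level structure.
* The HRV "feature signal" windowing means event-level HF/LF values share
  data across neighbouring events; they are valid task-level summaries,
  not independent event samples.
* The blink remover assumes a single dominant frontal low-frequency
  component; mixed ocular/muscle components would need a full ICA.
* AdaBoost-SVM can fail on tiny or degenerate training sets (no usable
  base learner); failures are reported, never silently imputed.
* Accuracies reported for real studies of this design (around 64–74% for
  self-report logistic regression) depend on covariance structure that is
  never published; the package's simulations recover above-chance accuracy
  in the 55–70% range under the documented defaults, and no attempt is
  made to tune the generator toward any externally reported accuracy.
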