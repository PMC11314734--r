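---
title: "Characterising toe extension force-time curves"
author: "toeforce"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Characterising toe extension force-time curves}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(toeforce)
```

## The measurement and its parameters

Great toe extension strength (GTES) is measured by asking a seated subject
to extend the hallux against a force sensor as hard as possible for 10 s.
The device samples force at 50 Hz, so one trial is a 500-point
force--time curve, stored as a two-column text file (time in seconds,
force in kilograms).  The curve carries more information than the peak
alone: how quickly force is developed and how steadily it is held both
reflect the muscle's physiological state.

`extract_features()` reduces a trial (after conversion to newtons,
$F = 9.80665 \, m$) to five parameters:

* **Peak force** $F_{\max}$ (N): the maximum sample.
* **Rise time** $t_{80}$ (s): the time of the first sample at or above
  $0.8\,F_{\max}$, measured from trial start.  The 80% cut-off is used
  because essentially all motor units of a muscle group are recruited
  near 80% of a maximal voluntary contraction, which makes the crossing
  a standardised end point of the recruitment phase.
* **Average force after the crossing** $\bar F_{80}$ (N): the mean of all
  samples from the first crossing to the end of the trial — a steadiness
  / endurance summary of the hold phase.
* **Percent at or above average** (%): the share of *all* samples in the
  trial at or above $\bar F_{80}$.
* **Rate of force development** $\mathrm{RFD} = 0.8\,F_{\max} / t_{80}$
  (N/s).

All threshold comparisons use "at or above" (`>=`), and ties at the peak
are resolved by the *first* crossing of the 80% threshold.

### Decisions where the definitions leave room

Three places in these definitions are genuinely open, and the package
fixes them as follows:

* **Rise-time origin.** $t_{80}$ is measured from the start of the
  recording, not from a detected force onset: no onset-detection rule is
  part of the protocol, and adding one would introduce a tunable detector
  into an otherwise parameter-free definition.  Device files starting at
  $t = 0$ and at $t = 0.02$ s are both accepted.
* **Rise-time floor.** If the very first sample already meets the
  threshold, $t_{80}$ would be 0 (or the time origin) and the RFD would
  be infinite.  The package floors $t_{80}$ at one sampling interval
  (0.02 s at 50 Hz) and flags the trial `rise_floor`.  Real maximal
  contractions never start at 80% of peak, so the flag marks data worth
  inspecting rather than a routine case.
* **The reference average for the percentage.** The percent-above
  parameter could be anchored to the post-crossing average or to the
  whole-trial mean.  The package defaults to the post-crossing average
  $\bar F_{80}$ — the only average defined alongside the other
  parameters — and exposes `pct_reference = "whole_trial"` as a
  configuration switch, so both conventions are computable.

## Ingestion and the missing-data rule

Trial files occasionally end a few samples short of the 10 s window.
These end-of-trial gaps are the only missingness the measurement
produces, and they are repaired by repeating the last recorded value
(`impute_tail()`), but only when the gap is shorter than 10 samples —
a strict limit, configurable via `ingest_config()`.  Non-finite values
in the interior of a trial indicate corruption rather than early
termination and are rejected outright.  The sampling rate is inferred
from the median time step; deviations beyond 1% of the nominal 50 Hz
raise a warning and flag the trial rather than failing, since a slightly
mis-clocked but structurally sound trial is still analysable.

## The synthetic cohort generator

No public raw GTES dataset exists, so validation uses synthetic cohorts
with known ground truth.  `simulate_trial()` uses the minimal shape that
exhibits the parameters of interest — a fast rise to a noisy plateau:

$$F(t) = P\,(1 - e^{-t/\tau})\,(1 + \epsilon_t), \qquad
  \epsilon_t \overset{iid}{\sim} N(0, c_v^2),$$

clipped at zero, where $P$ is the plateau force (N), $\tau$ the rise
time constant (s), and $c_v$ the within-trial noise level.  A logistic
rise is available behind the `shape` switch.  For a noiseless trial with
a window much longer than $\tau$, the 80% crossing sits at
$t_{80} = \tau \ln 5$; at a finite window $T$ the peak is
$P(1 - e^{-T/\tau})$ and the exact crossing is
$t^\ast = -\tau \ln\!\big(1 - 0.8\,(1 - e^{-T/\tau})\big)$.  The test
suite checks both: the finite-window closed form at the 10 s study
duration, and the $\tau \ln 5$ identity on 60 s trials, where it is
valid across the whole $\tau \in (0.1, 4)$ s range of interest.

`simulate_cohort()` draws per-subject parameters from truncated-normal
between-subject distributions defined by `group_profile()`s, one per
(age group, sex) stratum.  The default profiles are calibrated to
reference summary statistics of a 31-adult pilot cohort
(`pilot_reference_means()`): each stratum's plateau is set to its
observed mean (SD) peak force and $\tau$ is back-solved from the
observed mean (SD) rise time as $\tau = t_{80}/\ln 5$.  The stratum
sizes (older males 4, younger males 5, older females 13, younger
females 9) are the unique non-negative integers that reproduce the
reference marginal means of the male and female peak force to the
printed precision, given the margins of 17 older / 14 younger and
9 male / 22 female.  Height and weight are drawn per sex, BMI is derived
as weight/height², and grip strength per stratum.  The default
within-trial noise is $c_v = 0.05$, a typical steadiness of a maximal
isometric hold; the between-subject SDs are taken from the same summary
table.  This is a calibration of a convenient generative family, not a
claim about the true data-generating process.

`induce_correlation()` regenerates one covariate (grip strength by
default) as a Gaussian copy correlated at a chosen $\rho$ with the
per-subject true plateau, preserving the covariate's marginal moments —
giving tests a cohort whose feature--covariate correlation is known
exactly.

### What the generator does and does not emulate

It reproduces the curve geometry (fast rise, noisy plateau), the group
structure and between-subject spread of the parameters, and the
demographic marginals.  It does **not** emulate band-limited
physiological tremor spectra, within-subject repeat-trial variability
(the protocol collects a single trial), fatigue-related late decline, or
non-Gaussian parameter distributions.  Tests passing on synthetic
cohorts therefore validate the *pipeline arithmetic and statistical
machinery*, not claims about real toe-strength populations.

### A known property of the peak under within-trial noise

Because the peak is defined as the *maximum* sample, it is upward-biased
under within-trial noise: the maximum of $n$ roughly independent noisy
samples near the plateau exceeds the plateau by about
$c_v \sqrt{2 \ln n}$ on average — around 5% of the plateau at
$c_v = 0.02$ with 500 samples, several times the noise level itself.
This is a property of the sample-maximum definition, not an
implementation artefact; the validation suite measures the recovery
error rather than assuming it is of the order of the noise.  Analyses
comparing groups are unaffected (the bias is common to all trials at a
given noise level), but absolute peak values from noisy recordings
should be read with this bias in mind.

## Statistical analyses

`group_stats_report()` mirrors the traditional analysis of such cohorts:
mean (SD) descriptives per stratum, independent-samples t-tests between
sexes and between age groups, a two-way ANOVA per parameter, and Pearson
correlations of the parameters with grip strength and BMI, overall and
within age groups, with Shapiro--Wilk normality screening per variable
and stratum.

Choices where the convention is unstated:

* **Welch t-test by default** (`var_equal = FALSE`): the strata of
  interest are far from balanced (9 males vs 22 females), where the
  pooled-variance test is anti-conservative under variance
  heterogeneity.  Student's form is available by configuration.
* **Type-II sums of squares** for the unbalanced 2×2 ANOVA (via
  `car::Anova`), which are invariant to factor order and coincide with
  type-I on balanced designs (tested).
* **Pearson correlations** with normality *flags* rather than an
  automatic switch to Spearman: non-normal variables are marked so the
  reader can discount them, and Spearman is available by configuration.
* **No multiple-testing correction** is applied; every report carries a
  note saying so.  Significance is marked `*` at p < 0.05 and a trend
  `^` at p < 0.10.

`group_differences()` reports signed mean contrasts with a stated
convention (male − female, younger − older; for rise time additionally
the reversed contrasts, since the slower groups have the *longer* rise
time and that is the direction usually reported).

## Raw-curve classification

`build_dataset()` stacks the raw 500-point curves — not the extracted
features — into a matrix with binary labels (age group or sex), and
`evaluate_split()` / `evaluate_cv()` run the three model families suited
to small time-series samples: k-nearest neighbours (k = 5 or 10,
Euclidean), an RBF-kernel SVM, and a 100-tree random forest.

* **Splits and folds are stratified** so every part retains both classes
  despite the 9-vs-22 imbalance; a dataset whose minority class falls
  below 35% prints an imbalance note, since rank-based scores degrade
  with imbalance.
* **Split fractions default to 45/25/30** train/validation/test.  With
  31 subjects this yields validation and test sets of 7--10 subjects;
  the exact proportions are configurable and nothing downstream depends
  on them.
* **Standardisation** is fit on the training rows only (kNN and SVM are
  scale-sensitive) and is toggleable.
* **AUC** is computed in-package as the rank-based (Mann--Whitney) form
  with midranks for ties — the probability that a random positive
  outranks a random negative — and is cross-checked against an
  independent ROC implementation in the tests.  Continuous scores are
  the positive-class neighbour fraction (kNN), the decision value
  oriented toward the positive class (SVM), and the positive-class vote
  fraction (random forest).
* **Determinism**: every evaluation is a pure function of
  (dataset, model, seed); all randomness is drawn under an explicit seed
  and the caller's RNG state is restored.

With ~31 subjects, single-split accuracies are quantised in steps of
10--14 percentage points and AUCs move substantially between seeds;
reported numbers should be read as feasibility signals, not stable
performance estimates.

## Validation study sizes

The bundled validation suite uses: 1,000 random trials for
oracle-equivalence of the feature definitions; 100 noiseless trials for
the rise-time analytics; 200 noisy trials for peak recovery; 1,000
Monte-Carlo replicates for t-test and ANOVA type-I calibration
(3·SE acceptance bands); 10 cohorts of n = 1,000 for correlation
recovery at $\rho = 0.55$ (averaging replicate correlations tightens the
Monte-Carlo error well below the ±0.05 acceptance band); and 200
label-permutation replicates for classifier null behaviour.  These sizes
put Monte-Carlo noise comfortably below each acceptance band while
keeping the full suite to a few minutes on one core.

## Known limitations

* The pipeline analyses one trial per subject; repeated-trial designs
  would need an aggregation policy and mixed-effects analyses.
* No smoothing or filtering is applied to the force signal, by design;
  heavily contaminated recordings should be cleaned upstream.
* The generator's calibration targets are summary statistics, so
  synthetic cohorts reproduce means, SDs and margins — not the joint
  distribution of the real cohort.
* The peak's sample-maximum bias under noise, discussed above.
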