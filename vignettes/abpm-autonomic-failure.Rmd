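---
title: "Screening for autonomic failure from 24-hour blood pressure profiles"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Screening for autonomic failure from 24-hour blood pressure profiles}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(abpmaf)
```

## The clinical problem

Cardiovascular autonomic failure (AF) complicates Parkinson's disease in
roughly a third of patients. It disrupts reflex control of blood pressure,
producing orthostatic hypotension, supine hypertension, loss (or inversion)
of the nocturnal blood-pressure fall, and exaggerated pressure variability.
The diagnostic gold standard — cardiovascular autonomic reflex testing with
beat-to-beat monitoring — is confined to specialised autonomic units. In
contrast, 24-hour ambulatory blood pressure monitoring (ABPM) is cheap,
widely available and performed in the patient's own environment.

`abpmaf` implements a complete analysis chain that turns a raw ABPM
recording (cuff readings every 15 minutes plus a diary of sleep, wake and
meal times) into a set of autonomic-dysfunction markers, and combines them
in a linear discriminant classifier for AF. The reference diagnosis is the
reflex-testing rule: AF is present when the cardiovagal plus adrenergic
subscores of a sudomotor-free composite autonomic score sum to at least 2
(`af_diagnosis()`); the subscores themselves are inputs, their derivation
from reflex-test waveforms is out of scope.

## The ABPM parameter set

`extract_features()` derives, per recording (all windows half-open
`[a, b)` unless stated; thresholds live in `feature_config()`):

* **Period means and SDs.** Systolic, mean-arterial and diastolic averages
  over 24 h, daytime and night-time, plus systolic sample SDs (n − 1).
  Night is every diary interval `[sleep onset, next awakening)`. If the
  cuff file lacks mean arterial pressure it is derived as
  `dbp + (sbp − dbp)/3` and flagged.
* **Pressure loads.** Percentage of readings at or above the reference
  values: 135/85 mmHg by day, 120/70 mmHg by night.
* **Reverse dipping.** Day−night difference of mean systolic pressure
  ≤ 0 mmHg; the boundary case (equal means) counts as reversed.
* **Weighted variability (w-BPV).** Day and night systolic SDs averaged
  with weights equal to the day and night durations taken from the diary;
  "increased" above 11 mmHg.
* **Postprandial hypotension (PPH).** For each diary meal, reference = mean
  systolic value of the last three pre-meal readings; positive when the
  minimum in `(meal, meal + 120 min]` falls at least 20 mmHg below it.
* **Morning hypotensive episodes.** Count of readings between awakening
  and lunch whose systolic value is at least 15 mmHg below the 24-h mean
  ("at least" read inclusively: `sbp ≤ mean − 15`). Lunch is the first
  diary meal at or after 11:00; an optional fallback window of
  awakening + 5 h is used (and flagged) when no such meal exists.
* **Awakening hypotension.** At least one episode within 90 minutes of
  awakening, bounds inclusive.

Readings are validated on ingest (`sbp > dbp`, plausibility bounds 40–300 /
20–200 mmHg, strictly increasing timestamps, a 20–30 h span, and at least
70% of the expected 15-min slots by default); malformed rows are counted
and reported, never silently dropped.

Two genuinely open choices were resolved as follows. The SD features feed
the classifier as *systolic only* (24-h, day, night), because every
reported SD in the source domain (group tables, w-BPV, daytime systolic
SD) is systolic. Day/night assignment uses diary times, with the fixed
07:00/23:00 clock fallback available but flagged, since diary-based
splitting is the guideline-preferred method.

## The discriminant model

`fit_lda()` is a first-principles two-class Gaussian linear discriminant.
With class means $\mu_+,\ \mu_-$ and pooled covariance $S$,

$$w = S^{-1}(\mu_+ - \mu_-), \qquad
c = w^\top \frac{\mu_+ + \mu_-}{2} - \log\frac{\pi_+}{\pi_-},$$

and a patient is classified AF+ when $w^\top x > c$ (strictly: the exact
midpoint under equal priors is negative). $S$ is the pooled
*maximum-likelihood* covariance (within-class scatter divided by $n$),
which makes the fit exactly invariant under duplication of the sample;
predictions are also invariant to affine rescaling of any feature, so
booleans enter as 0/1 and nothing is standardized. Priors default to the
empirical class frequencies (the clinical prevalence reading); equal
priors are available.

Several extracted features are exact or near-exact linear combinations of
others (the 24-h mean of a component is a slot-weighted combination of its
day and night means; w-BPV is a fixed combination of the two SDs whenever
all patients share diary times). The pooled covariance is therefore often
numerically singular. When its condition number exceeds $10^{10}$ a ridge
term $\lambda\,\mathrm{tr}(S)/p$ with $\lambda = 10^{-6}$ is added; with
regularization disabled the fit aborts naming the collinear columns. The
ridge is small enough that it does not measurably perturb predictions on
well-conditioned data, and it breaks exact affine invariance only for
singular inputs.

`evaluate_lda()` reports **both** resubstitution and leave-one-out
cross-validated performance, clearly labelled. A single headline accuracy
with no cross-validation statement is most naturally read as
resubstitution (apparent) accuracy, but resubstitution is optimistic at
$p = 21$ features on $n = 80$ patients, so the honest LOOCV figure is
always computed alongside. K-fold evaluation is seeded; a training fold
that loses a class is merged with its neighbour with a warning.

## Diagnostic-accuracy statistics

* `confusion_metrics()`: accuracy, sensitivity, specificity, PPV, NPV with
  binomial intervals; zero-denominator metrics are flagged undefined, not
  reported as 0. Accuracy always satisfies the prevalence-weighted
  identity `acc = prev·sens + (1−prev)·spec`.
* `proportion_ci()`: Clopper–Pearson exact by default (the interval style
  of era-typical clinical software; the source tables do not state their
  method), Wilson by flag.
* `roc_analysis()`: empirical ROC over all distinct marker values;
  trapezoidal AUC, which equals the tie-corrected Mann–Whitney
  concordance exactly; Hanley–McNeil interval for the AUC (DeLong-style
  intervals were deliberately not added — the Hanley–McNeil form matches
  the reporting style of the clinical software generation the analysis
  emulates); Youden-index cut-point with ties broken toward the more
  sensitive threshold.
* `odds_ratio_2x2()`: cross-product odds ratio, Woolf log-scale interval,
  Haldane–Anscombe 0.5 correction (flagged) for zero cells.
* `logistic_fit()`: maximum-likelihood logistic regression via `stats::glm`
  (IRLS), Wald intervals, with quasi-complete separation detected and
  flagged; on a saturated single-binary-predictor fit the odds ratio
  equals the 2×2 cross-product to numerical precision, an identity the
  tests exercise.
* `group_compare()`: t-test vs Mann–Whitney chosen by a Shapiro–Wilk check
  (delegated to `stats`), chi-square vs Fisher by the expected-cell-below-5
  rule.

Display rounding follows the apparent convention of the printed clinical
tables: integer percentages rounded half away from zero, odds ratios to
two significant figures. No multiplicity correction is applied to the
single-parameter tables (the source analysis corrects only multi-group
comparisons, which are out of scope here).

## The synthetic cohort generator

No patient-level data accompany the source study, so `generate_cohort()`
provides cohorts with the *group-level* statistical structure of the
published population: n = 80, AF prevalence 36.25%, and per-group daytime
and night-time systolic means (122 ± 10 / 109 ± 11 without AF, 118 ± 8 /
122 ± 17 with AF), morning hypotensive-episode Poisson rates (0.4 / 3.4),
postprandial-drop probabilities (0.46 / 0.58) and covariate distributions,
all fixed in `cohort_config()` as the package's study conditions.

Design of the generator:

* Patient-level day and night means are **bivariate normal with
  correlation 0.5**. Day and night pressures correlate within a patient;
  with the group means and SDs above, the analytic reverse-dipping
  probabilities are $\Phi(-13/\sqrt{221 - 110}) \approx 0.11$ (no AF) and
  $\Phi(4/\sqrt{353 - 136}) \approx 0.61$ (AF), matching the published
  prevalences (10% / 58%) without any per-feature tuning. This single
  correlation was fixed a priori on that argument.
* The 96-slot series is period mean plus Gaussian reading noise (patient-
  level noise SD drawn per group; night noise 80% of day). No within-day
  autocorrelation is modelled.
* Morning dips are rectangular 1–2-slot depressions placed between
  awakening and lunch, with depth drawn 20–28 mmHg below the 24-h mean so
  the ≥ 15 mmHg criterion is robust; a Poisson-many count per patient.
  Postprandial troughs (30 mmHg below the daytime level, 2 slots) are
  injected after lunch or dinner only, keeping the morning window clean so
  injected dip counts remain exactly recoverable on the noise-free
  configuration (`noise_scale = 0`).
* The daytime baseline is compensated for injected events so the daytime
  template mean equals the drawn day mean; the configured group means are
  therefore recovery *targets* for the extracted means.
* Diastolic pressure is systolic minus a patient-level pulse pressure
  (Normal(45, 5), truncated at 25); mean arterial pressure is the
  third-of-pulse formula plus small measurement noise (so the feature
  matrix is not exactly collinear, as with a real oscillometric device).
* One master seed; each patient draws from an independent substream, so
  enlarging a cohort never changes earlier patients.

What the generator does **not** emulate — and hence what passing tests do
not establish about real recordings: physiologic autocorrelation and
activity-driven daytime variability, medication-cycle effects, cuff
artefacts, missing-data patterns, and any dependence of episode *shape* on
autonomic physiology. Emergent quantities that the generator does not
target (w-BPV > 11 prevalence, PPH prevalence, load distributions, and the
extracted episode counts, which exceed the injected Poisson rates because
noise also crosses the mean-relative threshold) are documented as
emergent and are not asserted against the published table.

## Problem sizes and verification

The test suite validates the statistical identities on small constructed
instances (closed-form one-dimensional discriminants, brute-force Fisher
ratio maximization, pairwise-concordance AUC oracles on 100 random
instances, root-finding oracles for the exact binomial interval, 1000
binomial replicates at n = 80 for interval coverage) and the pipeline on
synthetic cohorts of 30–80 patients, with one 2000-patient cohort used to
check calibration recovery of the group structure (nocturnal means within
1 mmHg, reverse-dipping prevalences within a few points). These sizes were
chosen so the full suite runs in about a minute on a laptop while keeping
Monte-Carlo error well inside the asserted bands. The end-to-end ordering
property — the discriminant beating every single parameter at
resubstitution — is asserted on the default 80-patient cohort; at that
sample size ties with the strongest single marker occur on some seeds,
which is the expected behaviour of an 80-patient comparison, so the
assertion is tied to the default configuration.

## Known limitations

* The package evaluates *markers* of autonomic failure against a
  reference label; it does not diagnose. The discriminant's coefficients
  are estimated under an equal-covariance Gaussian working model that the
  binary features clearly violate (they enter as 0/1), which is standard
  practice but a model misspecification nonetheless.
* Resubstitution accuracy at p = 21, n = 80 is optimistic; compare the
  LOOCV figures that every report includes.
* The lunch rule (first diary meal at or after 11:00) and the fixed
  fallback windows are conventions; recordings with unusual schedules
  should rely on accurate diaries.
* Timestamps are local clock time at minute resolution; recordings
  crossing daylight-saving changes are not handled specially.
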