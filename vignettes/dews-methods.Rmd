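---
title: "Dynamic early warning scores: models, conventions and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dynamic early warning scores: models, conventions and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Ward patients deteriorate gradually, and the standard UK response is the
National Early Warning Score 2 (NEWS-2): seven vital-sign parameters are
each banded into 0–3 points (supplemental oxygen: 0 or 2) and summed to a
0–20 total that triggers escalation at 5 and 7. NEWS-2 is deliberately
simple — it can be computed on paper — which discards two kinds of
information that electronic observations carry: the *granularity* of each
measurement (a heart rate of 131 and one of 170 both score 3) and its
*trajectory* (a heart rate that has climbed 30 beats/min over twelve
hours scores the same as one that has sat there for a week).

This package implements a dynamic early warning score (DEWS): an
L2-regularised logistic regression over 38 raw and time-series-engineered
features of the observation history, producing a probability of
deterioration for every observation set. Two outcomes are supported:
death or ICU admission within 24 h (`d_icu`), and clinically significant
deterioration — an annotated event requiring a change in treatment —
within 4 h (`csd`). The package also provides the full evaluation
apparatus for comparing such a score against NEWS-2 (bootstrap CIs,
matched cut-points, event-window detection) and a synthetic ward-cohort
generator so the whole pipeline is testable without access to restricted
hospital data.

## NEWS-2 scoring

The scorer is table-driven: `inst/extdata/news2_bands.csv` holds the
published chart (parameter, scale, oxygen status, band edges, points) and
`news2_score()` performs only lookups against it. Conventions that the
chart itself does not fix:

* **Granularity.** Measured values are snapped to the chart's grid before
  banding — respiration, pulse, pressure and SpO2 to the nearest integer,
  temperature to one decimal. Whether the source system rounded or
  truncated is unknowable from a chart defined on integers; rounding is
  the neutral choice and is applied consistently.
* **Consciousness.** The five-level ACVPU scale cannot distinguish new
  from chronic confusion, so "Confused" scores 3 like Voice, Pain and
  Unresponsive — the conservative reading of the guidance.
* **Scale choice is episode-level.** An episode with any observation set
  labelled "O2 sats scale 2 (chronic respiratory disease)" is scored on
  Scale 2 (target saturations 88–92%) throughout. A per-observation rule
  would let the scale flap with data-entry habits.

An independently transcribed if-chain oracle of the same chart lives in
the test suite; an acceptance test sweeps every band boundary ±0.1 for
every parameter, both scales, on and off oxygen, and requires 100%
agreement.

## The 38-feature manifest

Eleven static features describe the current observation set: hinge
splits (distance above / below the normal band, floored at zero) for the
four U-shaped vitals — heart rate, respiratory rate, systolic pressure,
temperature — a low-side hinge only for SpO2 (supranormal saturation is
not a risk signal), the inspired-oxygen ordinal, and the ACVPU ordinal
(Alert = 0 … Unresponsive = 4). Inspired oxygen has mixed units (L/min
or %), so both are mapped to a six-level ordinal (None = 0 … Very
high = 5) by an editable resource table
(`inst/extdata/fio2_mapping.csv`): 1–2 L/min or 24–28% is Low, 3–5 or
29–40% Low-moderate, 6–9 or 41–60% Moderate, 10–15 or 61–80% High,
above that Very high. These are conventional delivery-device bands; the
file exists precisely so a site can swap its own.

Twenty-one dynamic features add, for each of seven channels (the five
vitals plus the two ordinals): the difference from the previous
observation (0 when none exists), and the mean and sample SD of the up
to five most recent observations, undefined below three. Six trajectory
categories complete the manifest, one per physiological channel
(consciousness excluded): 0 normal-stable, 1 normal-unstable,
2 outside-improving, 3 outside-stable, 4 outside-worsening, judged from
the current value against the channel's normal band and the
least-squares slope (units/hour) of the window.

Parameters someone may want to tune, with defaults and reasons:

* **Normal bands** are the NEWS-2 zero-score bands (HR 51–90, RR 12–20,
  SBP 111–219, T 36.1–38.0, SpO2 ≥ 96 on Scale 1 / 88–92 on Scale 2;
  the oxygen ordinal's "normal" is 0). No separate normal range is
  defined by the NEWS-2 chart beyond its zero-score bands, and reusing
  those bands keeps the two scores commensurable.
* **Slope tolerance** defaults to band width / 24 per hour and the
  **stability (SD) tolerance** to band width / 8. Both scale with the
  physiological range of the channel — a 1.6 beats/min/h drift on heart
  rate and a 0.08 °C/h drift on temperature are then "the same amount"
  of trend. Nothing in the method prescribes values; these are design
  choices, exposed as arguments of `slope_category()`.
* **Undefined rolling statistics** (fewer than three observations) are
  encoded as 0 *on the raw scale*, before normalisation, and the row is
  kept. The first two observation sets of each episode are excluded from
  scoring anyway, so this arises only for rows 3–4 of an episode whose
  early sets were incomplete; zero on the raw scale is an explicit
  "no signal" convention rather than an imputation.
* **Difference features are raw differences**, not per-hour rates; with
  broadly 4-hourly observations the two are nearly proportional, and raw
  differences avoid exploding when two sets arrive minutes apart.

Feature construction is causal by design: the vector at index *i* is a
function of the episode's observations up to and including *i*. A
truncation-equivalence test enforces this.

## Labels and splits

An observation at time *t* is positive iff a qualifying event occurs in
the window (*t*, *t* + horizon]: open at *t* — an event at the very
instant of the observation is a concurrent detection, not a prediction —
and closed at the horizon. Episodes may contain several annotated
deterioration events and every observation is labelled against all of
them. Episodes are truncated at the first death or ICU admission: a
score has no job to do after the terminal event. Both conventions are
arguments of `label_observations()`.

Train/validation splits are episode-level (no patient contributes to
both sides), either temporal — by each episode's last observation
against a calendar cutoff, matching the "train on earlier years,
validate on the last year" design — or random with a reproducible seed,
matching the annotated-subset design.

## Model

`train_dews()` fits ridge logistic regression (glmnet, `alpha = 0`) on
the normalised feature matrix. Normalisation constants (mean, SD per
feature) are estimated on training data only and stored on the model;
features constant in training get SD 1 and normalise to zero. The
regularisation strength is selected by ten-fold cross-validation that is
**grouped by episode** and **stratified on the episode-level outcome**
(any positive row). Stratified cross-validation alone does not say
whether folds may split a patient's rows; grouping is the standard
defence against within-patient leakage, and a dedicated test asserts no
episode ever straddles folds. The grid is seven
log-spaced inverse strengths C from 1e-3 to 1e3, translated to the
optimiser's penalty by λ = 1/(nC); the C maximising mean cross-validated
AUROC wins, ties broken toward the stronger penalty, and the model is
refit on all training rows at that strength. "L2 regularisation for
feature selection" cannot literally zero coefficients, so all 38
features are retained — shrinkage is the selection. The optimiser runs
at convergence threshold 1e-8 so that refits are bit-reproducible;
scoring is the closed form `plogis(intercept + coefficients · z)`.

## Evaluation

* **AUROC** is computed by the Mann–Whitney identity (midranks, ties
  count one half), which equals the trapezoidal ROC integral; an
  acceptance test checks exact agreement with brute-force pair counting
  on a thousand random instances.
* **AUPRC** is average precision — the step-function sum with tied
  scores handled as a block. Trapezoidal interpolation of PR curves is
  optimistic on heavily imbalanced data, which these are (a few percent
  positive). On the worked 4-point case (positives scored 0.9 and 0.4,
  negatives 0.5 and 0.1) the trapezoidal area is 11/12 but average
  precision is 5/6; this package returns 5/6, verified against an
  independent threshold-sweep oracle.
* **Bootstrap CIs** are percentile intervals over 500 resamples (the
  published design) of observation sets with replacement. Resampling
  rows ignores within-episode clustering, so an episode-level option
  exists (`unit = "episode"`) for sensitivity analysis; the row-level
  default matches the most literal reading of the source design. A
  coverage simulation (true AUROC 0.80, 200 repetitions) must land in
  [91%, 98%].
* **Operating points** call positive at score ≥ threshold. False
  positive and false negative rates are reported as percentages of
  *all* observation sets — the "how often does the ward get an alarm"
  convention — not of the negative/positive class.
* **Matched cut-points**: to compare DEWS with NEWS-2 ≥ 5 (or ≥ 7), the
  candidate threshold is chosen over the observed candidate scores so
  that its specificity (or sensitivity) is at least the reference's,
  taking the smallest (respectively largest) such threshold. When
  consecutive cut-points tie on the matched metric the rule therefore
  maximises the *other* metric at the matched level — which is exactly
  the comparison the matched tables are for. With ties this can make a
  "matched" point strictly better on the free metric even for a
  monotone transform of the reference score; the tests assert equality
  on the matched metric and dominance on the free one.
* **Event-window detection**: an event is detected by a score iff any
  observation of its episode in [t_event − 4 h, t_event] reaches the
  threshold; two scores yield a both / only-A / only-B / neither
  cross-tab whose cells must sum to the event total.

## The synthetic world

`generate_cohort()` emulates the *structure* of an electronic ward
observations dataset, not any particular hospital's case mix. Episodes
carry 6+ observation sets at gamma-jittered ~4 h spacing; vitals follow
stationary AR(1) processes (φ = 0.7 per step) around per-patient set
points drawn from truncated normals near textbook values; a quarter of
episodes are chronic-respiratory (SpO2 Scale 2) with lower saturation
set points; oxygen therapy escalates deterministically as the underlying
saturation falls, so the FiO2 ordinal co-trends with desaturation.
Fifteen percent of episodes deteriorate: a sepsis-like,
respiratory-failure or cardiovascular archetype superimposes
linear-plus-noise ramps (HR and RR up, SBP and SpO2 down, temperature
archetype-dependent) over an 8–20 h lead time ending at the event, with
consciousness dropping late in the ramp; about half of deteriorations
end in death or ICU admission (truncating the episode), and all carry an
annotated deterioration event with a code. Under these defaults the
24-hour death/ICU label sits at a few percent of observation sets, inside
the 1–8% band the tests assert.

What the generator does **not** emulate: real case-mix and seasonality,
measurement artefacts and documentation lag, the annotation-selection
bias of a manually labelled cohort (beyond an optional maximum-NEWS-2
filter via `max_news2()`), and the acuity of a real respiratory ward —
the synthetic population is deliberately less sick, so absolute AUROCs
and detection rates here say nothing about the published ones. A green
dynamics-advantage test establishes that *when deterioration is a trend*,
trend features beat a static snapshot — a qualitative property — and no
more.

`generate_from_logistic_truth()` replaces the event mechanism with
labels drawn from a known logistic model on the engineered features, so
that ridge recovery of coefficient signs and of the truth model's AUROC
can be tested against a stored oracle.

## Sample-size planning

`required_positives()` implements the normal-approximation comparison of
two ROC areas with the Hanley–McNeil variance
V(A) = [A(1−A) + (n⁺−1)(Q₁−A²) + (n⁻−1)(Q₂−A²)]/(n⁺n⁻),
Q₁ = A/(2−A), Q₂ = 2A²/(1+A), standard error
√(V₁ + V₂ − 2ρ√(V₁V₂)), and returns the smallest number of positives
attaining the requested power. The reference method leaves three things
unstated: the test's sidedness, the correlation ρ between the two AUC
estimates (both scores are computed on the same patients), and the
negative:positive allocation. All three are explicit arguments,
defaulting to the transparent assumptions (two-sided, ρ = 0, equal
allocation).

For the planning figure of 463 positives (0.80 vs 0.85 at 80% power), a
numerical sweep of the assumption space shows that two-sided α = 0.05,
equal allocation and ρ = 0.15 reproduces 463 exactly — and is the only
combination on a ρ grid of 0.01 across allocation ratios 0.5–17.5 that
does. The defaults give 544 (ρ = 0) rather than 463, so the documented
assumption set must be passed explicitly, as `scripts/acceptance.R` and
the acceptance test do. A mild positive correlation between two scores
evaluated on the same cases is plausible; 0.15 should nonetheless be
read as *the assumption set consistent with the published figure*, not
as an estimate.

## Numerical choices and degenerate inputs

Timestamps are parsed as ISO-8601 with explicit offsets and compared as
absolute instants, so the 4 h and 24 h horizons are immune to DST and
mixed-offset files. Duplicate timestamps within an episode are kept in
file order (stable sort). Malformed rows are collected with line numbers
and dropped, fatal only above 10% of the file. Constant features
normalise to zero with a warning rather than dividing by zero. A
single-class training set is an error, not a silent degenerate fit;
fewer positive episodes than folds reduces the fold count with a
warning. Bootstrap resamples on which a metric is undefined are dropped,
erroring only above 20%. The matched-threshold search returns an extreme
threshold with a warning when the target is undefined (e.g. no
positives).

## Known limitations

The 38-feature manifest is a reconstruction — the published models'
exact feature list and coefficients sit in restricted supplementary
material — so coefficient-level comparisons are qualitative only.
Observation-level bootstrap understates CI width under strong
within-episode correlation; use the episode-level unit to check.
The CLI covers the pipeline but not orchestration (no config-file
merging beyond flags). Paediatric rule variants, NEWS (version 1),
and calibration/decision-curve analyses are out of scope.
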