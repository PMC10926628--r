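---
title: "Methods: screening for gynaecological malignancy from pre-referral search histories"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: screening from pre-referral search histories}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Symptomatic patients referred from primary care on an urgent
suspected-cancer pathway carry, in their own online search histories, a
record of symptom-driven information seeking that precedes the referral by
months. `querysift` implements a case-control analysis over such
histories: each patient contributes a stream of timestamped queries, a
referral date (day 0 of the timeline), a benign/malignant outcome, and
optionally a 20-symptom clinical questionnaire. The question is whether
the query stream separates malignant from benign outcomes, and how far
before referral the separation appears.

Everything downstream is expressed in whole days before referral
("offsets"): time of day is dropped at ingest, the referral day itself is
always excluded (searches on day 0 reflect the GP consultation, not the
pre-referral state), and histories are truncated to a 24-month lookback
(730 days).

## Health filtering

Raw logs are reduced to an analysis set in three ordered stages:

1. **Inclusion.** A query is kept if any of its normalized tokens
   (lowercased, accent-folded, punctuation-stripped) appears among the
   words of the medical-terms list. Matching is on exact word tokens, not
   substrings — "clubbing" does not match "club" — and each word of a
   multi-word phrase matches independently, so "club foot" deliberately
   admits "club music tonight" to the next stage. The bundled list covers
   symptoms, diseases and drugs in English with French and Spanish
   colloquial equivalents; it is a synthetic stand-in for a larger
   proprietary list and is replaceable via `read_lexicon()`.
2. **Exclusion.** Queries matching an exclusion pattern are dropped:
   either a (trigger, context) word pair such as (cat, bleeding) — the
   mechanized form of a manual pass removing pet and irrelevant-organ
   queries — or a standalone stop phrase ("club music"). Patterns ship as
   an editable YAML file; mechanizing the manual step is what makes the
   filter reproducible.
3. **Dedup.** A query whose normalized text equals that of the immediately
   preceding retained query *from the same user* is dropped, regardless of
   the time gap between them. Users left with an empty filtered history
   are excluded from the cohort (and counted in the enrolment report).

Stage counts are returned as a `FilterReport`-style tibble and are
monotonically non-increasing; the filter is idempotent.

## Categories and weekly timelines

Each query is assigned to every one of the 14 curated symptom categories
that any of its tokens maps to (categories are not mutually exclusive).
The category list follows the field's convention and includes both
"pelvic organs" and "vagina or pelvic organs" as distinct labels.

`weekly_category_series()` bins categorized queries into weeks before
referral. Week `k` covers offsets `[7k - 6, 7k]`, so week 1 is the last
pre-referral week. Counts are summed per (outcome stratum, category,
week) and divided by the number of users in the stratum — *all* users,
not just those active that week, so the series reads as queries per
patient. Smoothing is a trailing 4-week moving average whose window
covers the current week and the three weeks *further from referral*;
this way no post-referral bin is ever used. At the far end of the series
the window shortens to the available weeks, which means a true average
at the edge at the cost of exact mass preservation there (the tests pin
down both behaviours); an interior impulse keeps its total mass exactly.

`estimate_onsets()` turns the malignant-minus-benign difference series
into a change-point per category by least-squares two-segment constant
fitting; the unsmoothed series gives the sharpest change-points.

## Featurization

A window `(T1, T2)` selects queries with offsets in
`[T2, T1]`, both inclusive, stored as positive days-before
(`window(630, 60)` = from 630 down to 60 days before referral).

Two representations:

* **Terms** — bag of unigrams and consecutive-word bigrams (bigrams never
  span query boundaries), raw occurrence counts, restricted to terms used
  in-window by at least 5 distinct patients. Counts rather than tf-idf or
  normalization: gradient boosting is scale-insensitive and the count
  representation matches how the features are described in this line of
  work. A binary presence/absence switch exists for sensitivity checks.
* **Categories** — the 14-dimensional count of query-category
  assignments (a multi-category query increments each of its categories).

The terms vocabulary is rebuilt inside every cross-validation training
fold: a term used only by the held-out patient never enters that fold's
feature space. The feature container carries per-user raw term counts so
the per-fold rebuild costs a document-frequency adjustment rather than a
re-tokenization. Outside cross-validation (e.g. the full-cohort model
applied to external controls) the vocabulary is built on all patients,
where leakage is not a concern.

## Classification and evaluation

The classifier is gradient boosting with 50 weak learners
(`xgboost`; depth 3, learning rate 0.1, logistic loss, row subsampling
1.0 — the depth/rate defaults are the library's conventional settings,
exposed in `model_config()`). With subsampling at 1.0 the fit is
deterministic, so repeated runs of a window return identical AUCs; the
`n_repeats` machinery (seeds `seed, seed + 1, ...`) matters only when
subsampling is enabled.

Evaluation is leave-one-out cross-validation: each patient is scored in
[0, 1] by a model trained on all others. AUC is computed in the
Mann-Whitney rank form with ties counting one half; it is verified in the
tests against brute-force pair counting and an independent ROC
implementation. A caveat worth knowing: on *signal-free* windows, LOOCV
AUC is biased below 0.5, because removing a positive patient lowers the
training prevalence and with it every score that tracks the base rate —
values around 0.35-0.45 on null windows are an artifact of the
resampling scheme, not evidence of anti-signal.

`sweep_windows()` evaluates a (T1, T2) grid — default T1 from 30 to 700
days in 30-day steps, T2 from 1 up to T1 − 30 — restricting each window
to users with at least one in-window query, and flagging (rather than
failing on) windows that leave fewer than two users in either class.
`compare_representations()` pairs two sweeps window by window and applies
an exact two-sided sign test (ties dropped), plus a mean difference
restricted to windows where the first representation's AUC exceeds 0.55.

## Sample-size-corrected AUC

Removing patients (e.g. by the engagement filter) shrinks the training
set, and AUC declines with sample size for small cohorts. The correction
measures that dependence directly: `auc_sample_curve()` draws 5 random
patient subsets (without replacement) at each requested size, runs LOOCV
on each, and fits AUC ~ size by ordinary least squares.
`corrected_auc()` then shifts an AUC measured on `n` patients along the
fitted line to the reference size: `raw + slope * (N - n)`, clipped to
[0, 1]. At `n = N` or with a flat curve this is an identity. (An
alternative formulation — evaluate the fitted line at `N` and offset by
the residual at `n` — is algebraically the same shift, so no switch is
offered.) The questionnaire-only model is low-dimensional and its
AUC-size regression is typically flat, so its AUC is reported
uncorrected.

## Engagement filter

Within a window `(T1, T2)`, a user counts as health-engaged if at least
one query in the *first half* of the window — offsets from T1 down to the
midpoint `T1 - floor((T1 - T2) / 2)`, inclusive — mentions a listed
medical condition. Only the first half is used: filtering on the half
nearest referral would preferentially remove benign patients and bias
the comparison. The bundled 120-entry condition list is a synthetic
stand-in for a much larger clinical list and is replaceable.

## Questionnaire association

For each questionnaire symptom, a 2x2 table cross-tabulates the
questionnaire flag against whether the patient searched for the symptom
(at least one filtered query over the full 24-month lookback containing a
mapped term — the mapping ships as an editable YAML stand-in).
Pearson's chi-squared without continuity correction is applied (the
expected-count-below-5 condition is reported as a caveat flag, not a
failure), with Bonferroni gating at `alpha / n_symptoms` (0.0025 for 20
symptoms at alpha 0.05). Zero-margin tables are marked not evaluable.

## Control populations

An external control population (users with no referral) is scored by a
model trained once on the full cohort. Controls are featurized exactly
like patients, with a pseudo-referral placed the day after their fixed
data period ends, so the last in-period day maps to offset 1. Controls
should pass through the same health filter first. Users who queried
gynaecological-cancer terms 10+ times across the data period and a
3-month lookahead (counted jointly by default; an either-period rule is
available) are excluded as plausibly already diagnosed. Score
distributions are compared as 10-bin histograms on [0, 1] (top bin
right-inclusive) via total-variation distance.

## The synthetic cohort generator

No patient-level search data of this kind is publicly available, so the
generator is a first-class module: every pipeline stage is exercised
against cohorts whose ground truth is known. Defaults encode the study
conditions the pipeline targets:

| parameter | default | meaning |
|---|---|---|
| `n_users` | 235 | cohort size |
| `malignant_prevalence` | 0.26 | P(malignant outcome) |
| `engagement_rate` | 0.65 | P(user makes condition queries at all) |
| `mean_health_queries` | 2208 | target mean filtered queries/user over 730 d |
| `rate_sigma` | 0.75 | lognormal spread of per-user condition-query rate |
| `symptom_rate` | 0.02/day | baseline per-category query rate |
| onset schedule | GI, pain 365 d; urinary, bleeding 140 d; bloating, gynaecological, menopause 70 d | day offsets where malignant rates switch on |
| rate multiplier | 3 | post-onset rate inflation in malignant users |
| `benign_signal` | 1 | benign users' (time-constant) symptom scale |
| `questionnaire_noise` | 0.1 | flag-flip probability vs latent exposure |

Benign users are symptomatic referrals, not healthy controls: they carry
the same baseline symptom rates, only the staged onsets are
malignant-specific. Non-engaged users still emit symptom and decoy
queries but no condition queries, so the engagement filter has an exact
target subpopulation. Query texts are drawn from the lexicon's own
pools, with two orthogonality rules so that ground truth stays exact:
condition texts avoid category keywords, and category pools avoid
single-word condition names. All randomness flows through one seeded
sequential stream — generation is not parallelized, and a single stream
keeps cohorts byte-reproducible from the configuration alone.

The true post-onset effect size is not identifiable from published
aggregate results; the multiplier of 3 was fixed once so that onset
ordering and window recovery are detectable at cohort sizes of 200-500,
and is documented here as a synthetic choice rather than an estimate.

**What passing tests do and do not show.** The generator's outcome signal
lives, by construction, in the category rates. Two consequences: the
synthetic task is easier than the real one (near-referral windows reach
AUCs far above those reported on real patients), and the categories
representation is at least as strong as the terms representation on
synthetic data — the reverse of what richer real query text produces. The
generator also makes no attempt at natural language, demographic
covariates, recall bias in questionnaires, or seasonality. Passing the
recovery suites therefore validates the *machinery* (windowing,
filtering, leakage-free evaluation, correction arithmetic, onset
detection), not the clinical effect sizes.

## Problem sizes and numerical choices

Tests and the acceptance script run the study-scale structure at reduced
query volume: `mean_health_queries` 250-500 instead of 2208, control
populations of a few hundred, cohort sizes 40-500 with the spec-level
checks at n = 200 (window recovery, permutation null), n = 500 (onset
ordering, marginal volume) and n = 235 (acceptance script). Reported
percentages round half away from zero to one decimal, matching how such
figures are conventionally printed; the mean-queries-per-patient summary
is floored to a whole number. AUC ties take half credit; the change-point
fit breaks exact ties by the earliest minimizing week. Degenerate cases
are first-class: empty fold vocabularies score at training prevalence,
sparse sweep windows are flagged unevaluable, zero-margin contingency
tables are marked not evaluable, and zero-vector controls are scored (and
flagged), not dropped.

## Limitations

The bundled lexicon, condition list and symptom-term map are compact
synthetic stand-ins; analyses of real data should substitute full
clinical resources. Calendar effects, multilingual tokenization beyond
accent folding, spelling correction and stemming are out of scope. The
sample-size correction is a linear extrapolation and should not be pushed
far beyond the measured size range. LOOCV's null bias (above) should be
kept in mind when reading AUCs near chance.
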