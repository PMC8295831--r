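---
title: "Methods: from headache e-diary to monthly outcomes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: from headache e-diary to monthly outcomes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(headachediary)
```

`headachediary` implements a complete diary-to-outcome pipeline for
smartphone headache diaries: attack-level ICHD-3 classification, expansion
of attacks to calendar days, 28-day monthly aggregation, 90-day
episodic/chronic subgrouping, daily-use cohort selection, and paired
baseline-vs-follow-up inference. This vignette documents the model, the
tunable parameters, the synthetic-data world used for verification, and the
design decisions taken where the underlying methodology leaves room.

## The diary model

Three tables describe a diary: user profiles (sex, age, prior headache
diagnosis, first day of app use), headache attacks (start/end wall-clock
timestamps, maximal 0–10 NRS intensity, eight boolean symptom flags), and
medication intakes (free-text drug name and dose, timestamp, optional
migraine-specific flag). A fourth table of daily entries operationalises
"used the app every day": a `no_headache` entry on attack-free days. A day
counts as *covered* when it carries an entry or intersects an attack.

Two modelling commitments are worth making explicit:

* **Timestamps are local wall-clock, no timezone arithmetic.** Diary
  semantics are calendar semantics; durations are computed as clock
  differences (stored internally as UTC so daylight-saving shifts cannot
  silently add or remove an hour).
* **Overlapping attacks of one user are a validation error, not a merge.**
  Classification and day-expansion are defined per attack; silently merging
  overlapping records would invent semantics the data model does not have.

## Attack classification

The classifier is a deterministic rule engine. With the default
`classifier_config()`:

| parameter | default | meaning |
|---|---|---|
| intensity bands | mild 1–3, moderate 4–7, severe 8–10 | "moderate or severe" ⇒ ≥ 4; TTH's "mild or moderate" ⇒ ≤ 7 |
| migraine duration | ≥ 4 h, no upper bound | qualified-migraine conjunct |
| TTH window | 0.5–168 h | ICHD-3 tension-type duration range |
| triptan list | sumatriptan … frovatriptan | case-insensitive substring match on drug names |
| attribution window | [start − 1 h, end] | intakes attributable to an attack |

A *qualified migraine* lasts ≥ 4 h with feature A (≥ 2 of unilateral,
throbbing, intensity ≥ 4, aggravation by activity) and feature B (nausea ∨
vomiting ∨ (photophobia ∧ phonophobia) — the photo/phono pair is
conjunctive). Aura or an attributable migraine-specific intake overrides
everything. TTH requires the duration window, ≥ 2 *negated* pain features,
no nausea/vomiting and at most one of photo-/phonophobia. *Probable
migraine* fails exactly one qualified-migraine conjunct. Attacks satisfying
both TTH and probable migraine take the TTH label (the ICHD-3 "general rule
of hierarchy") unless the user reported a prior migraine diagnosis, in
which case they count as migraine; a probable-migraine-only attack is
likewise migraine with a prior diagnosis and OTHER without.

Design decisions worth flagging because the source methodology does not pin
them down:

* The NRS cut points (1–3 / 4–7 / 8–10) are the conventional tertiles and
  configurable.
* The TTH and probable-migraine operationalisations above are declared
  explicitly and mirrored, independently coded, in the test suite's
  truth-table oracle; the package and the oracle were written against the
  same stated rules, not against each other.
* Medication attribution needs a temporal join rule in a flat-file world;
  one hour before onset through attack end is used. An intensity of 0 with
  symptom flags set is classified normally (the intensity indicator of
  feature A is simply false).
* Recorded durations are used as-is; no untreated-duration correction is
  attempted for attacks treated with non-specific analgesics.

## Monthly outcomes and subgrouping

A month is 28 days from the first day of use; month 1 is the baseline. Per
user-month the pipeline reports MHD (days with any attack), MMD (days with
a MIGRAINE-labelled attack), AMD (days with any acute-medication intake,
triptan or not, regardless of attack linkage), and mean intensities.

* **Multi-day attacks** contribute every intersected calendar day — the
  outcomes are day-level, not attack-level.
* **Mean monthly intensity** is the mean over qualifying days of the day's
  maximal attack intensity, undefined (NA) in months with zero qualifying
  days. Averaging per-day maxima rather than per-attack values keeps the
  intensity outcomes consistent with the day-based frequency outcomes; the
  underlying methodology is silent here, so this is a declared choice, not
  inferred intent.
* **Diagnosis groups** use the first 90 days: chronic migraine at ≥ 45
  headache days including ≥ 24 migraine days (the per-30-day rates 15 and 8
  applied as 90-day totals, avoiding sub-month boundary artifacts), else
  episodic migraine at ≥ 5 migraine attacks, else OTHER. All three
  thresholds are configurable.
* **Daily-use cohorts** require every single day covered from first use
  through day 28 × m; one missing day excludes a user.

## Statistics

The paired *t* test is computed from the closed-form sums on
d = baseline − follow-up, so a declining outcome yields a positive mean
difference and positive CI; an increase yields a negative CI. The
repeated-measures ANOVA removes the between-subject effect and tests
`F = MS_time / MS_error` on `(k−1, (k−1)(n−1))` degrees of freedom; no
sphericity correction is applied by default (a Greenhouse–Geisser option
exists). Two-tailed α = 0.05 with no multiple-testing correction, matching
standard practice for this descriptive analysis type. Intensity outcomes
use pairwise-complete users per outcome (a user with zero headache days in
either compared month is excluded from that outcome only); frequency
outcomes use all users with both months observed. Degenerate inputs (fewer
than two pairs, zero variance of differences, constant matrices) raise
errors, and table builders convert those into `note`-marked non-computable
rows rather than fabricating statistics. Demographic percentages always use
available-data denominators: 920 females among 1047 users with recorded sex
is 87.87%, regardless of how many users did not record sex.

## The synthetic world

`generate_cohort()` simulates the cohort structure the analysis assumes.
Each user is latently a migraineur (default fraction 0.72) or a TTH-type
sufferer. On each day of month *m* an attack occurs independently with
hazard `h_m = baseline_daily_hazard × monthly_decline^(m−1)`; defaults are
`9.42/28` and `(6.39/9.42)^(1/6)`, i.e. an expected baseline MHD of 9.42
declining to 6.39 by month 7 — the calibration targets of the reference
cohort. `expected_mhd()` returns the closed form `28·h_m`. Attacks start
uniformly between 08:00 and 16:00 with lognormal durations (median 12 h for
migraineur-type, 4 h for TTH-type) truncated to the calendar day, so day
counts equal attack counts and the Binomial expectation is exact. Symptom
flags follow per-type profiles (migraineur: unilateral 0.7, throbbing 0.8,
intensity ≈ N(6, 1.5) clipped to 1–10, nausea 0.6, vomitus 0.2, photophobia
0.7, phonophobia 0.6, aura 0.2; TTH-type: bilateral, pressing, intensity
clipped to 1–7, no aura). Under these defaults roughly nine in ten
migraineur-type attacks classify as MIGRAINE — the profile probabilities,
combined with realistic medication behaviour, give ≈ 88–93% rather than a
higher figure, which is sufficient for the recovery tests that rely on MHD
(classification-independent) and directional MMD effects. Treated attacks
(probability 0.6) generate an intake 30 minutes after onset, a triptan with
probability 0.5 for migraineurs (recorded with a missing
`migraine_specific` flag, deliberately exercising the name-lookup path).
Demographics carry configured missingness (sex 32%, age 25%) and 87.9%
females among recorded.

Options off by default, because the stated world keeps expectations
closed-form: `allow_multiday` lets durations cross midnight (day-expansion
stress tests), `hazard_dispersion` draws per-user hazards from a Beta
distribution with preserved mean (the real cohort's baseline SD of 5.81
versus the Binomial SD ≈ 2.5 implies such overdispersion, but its
parameters are not identifiable from published aggregates), and
`chronic_frac`/`chronic_daily_hazard` add a high-frequency stratum to
populate the chronic-migraine subgroup.

What a green test does **not** establish: the generator has full daily
adherence by construction (no dropout, no backfilling), single-locale
wall-clock time, at most one attack per day by default, and symptom
profiles that are independent across flags given the latent type. Real
diaries violate all four; the generator verifies the pipeline's arithmetic
and inferential machinery, not the epidemiology of any real cohort. In
particular, the reference cohort's published baseline-to-month-7 changes
derive from proprietary user data and are *not* reproduced here — the
package demonstrates that a world calibrated to those means is recovered by
the pipeline within sampling error (±0.30 at n = 1500) and that the null
world (decline 1) preserves the nominal type-I error.

## Numerical and degenerate-input choices

* Durations are exact to the minute; generated timestamps are
  minute-aligned.
* `month_index` is pure integer arithmetic (`⌊days/28⌋ + 1`), exact at the
  day-28/29 boundary.
* Zero-variance difference vectors and constant matrices error with
  "degenerate: zero variance" rather than returning infinite statistics.
* Validation reports the first violated rule with table and row context and
  is total: every malformed input is rejected with a named rule, every
  valid one passes.

## Known limitations

No aura-subtype logic, secondary-headache red flags or medication-overuse
detection; no dropout or mixed-effects modelling; no lifestyle or weather
covariates. The 90-day diagnosis window uses totals rather than
calendar-month subdivisions, and months beyond the aggregation horizon are
simply ignored. These are scope boundaries, not accidents; see the README
for the analysis surface that is covered.
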