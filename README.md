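# headachediary

Classification and longitudinal analysis of smartphone headache e-diaries.

Electronic headache diaries record, for every headache attack, its start and
end, the maximal pain intensity on the 0–10 numeric rating scale (NRS), and
eight yes/no symptoms (unilateral, throbbing, worsening with activity,
nausea, vomiting, photophobia, phonophobia, aura), plus acute-medication
intakes. `headachediary` turns such raw diaries into the outcome measures
used in headache research — monthly headache days (MHD), monthly migraine
days (MMD), monthly days with acute medication use (AMD), and mean monthly
headache/migraine intensity — and compares them between baseline and
follow-up. It is aimed at researchers analysing mHealth diary exports and at
anyone who needs a tested, reproducible implementation of the ICHD-3
attack-classification rules.

## The rules and statistics at the core

**Attack classification (ICHD-3).** An attack is a *qualified migraine* when
it lasts ≥ 4 h and satisfies both

- **feature A**: ≥ 2 of {unilateral, pulsatile, intensity ≥ 4 (moderate or
  severe), aggravation by activity}, and
- **feature B**: nausea ∨ vomiting ∨ (photophobia ∧ phonophobia).

Aura or an attributable intake of a migraine-specific medication (a triptan)
forces the MIGRAINE label regardless of duration or features. Tension-type
headache (TTH) requires a duration in [30 min, 7 days], ≥ 2 negated pain
features (bilateral, non-pulsatile, intensity ≤ 7, no aggravation), no
nausea/vomiting, and at most one of photophobia/phonophobia. *Probable
migraine* fails exactly one of the three migraine conjuncts. Attacks meeting
both TTH and probable-migraine criteria follow the ICHD-3 "general rule of
hierarchy": TTH, unless the user reports a prior migraine diagnosis, in
which case MIGRAINE.

**Aggregation.** A month is 28 days from the first day of app use (month 1 =
baseline). MHD/MMD/AMD count calendar days; a multi-day attack counts every
intersected day. Chronic migraine over the first 90 days means ≥ 45 headache
days including ≥ 24 migraine days (15 and 8 per 30-day month); episodic
migraine means ≥ 5 migraine attacks.

**Inference.** Baseline vs follow-up uses the classical paired *t* test on
d = baseline − follow-up (so improvements give positive confidence
intervals), and comparisons across ≥ 3 months use one-way within-subjects
ANOVA, `F = MS_time / MS_error` with `df = (k−1, (k−1)(n−1))`. Demographic
percentages are always computed on the available (non-missing) data.

## Worked example

Simulate a daily-use cohort whose per-day attack hazard declines over seven
28-day months, classify, aggregate and compare baseline against month 7:

```r
library(headachediary)

cfg <- simulation_config(n_users = 300, months = 7, seed = 42)
coh <- generate_cohort(cfg)
cls <- classify_attacks(coh$collection)
table(cls$label)
#> MIGRAINE    OTHER      TTH
#>    11269      304     5037

out <- compute_monthly_outcomes(coh$collection, cls, months = 7)
paired_t_test(out$mhd[out$month_index == 1], out$mhd[out$month_index == 7],
              outcome_name = "MHD")
#> Paired t test [MHD]: n=300
#>   baseline 9.55 (SD 2.40)  follow-up 6.63 (SD 2.17)
#>   diff 2.920, t(299)=15.388, p=9.303e-40, 95% CI [2.547, 3.293]
```

The generator's defaults expect a baseline MHD of 9.42 declining to 6.39 by
month 7; the sample cohort reproduces that (9.55 → 6.63) and the paired test
confirms the decline (mean difference 2.92 days, CI entirely positive). The
full analysis surface — per-subgroup outcome tables, 90-day diagnosis
groups, demographics, repeated-measures ANOVA — comes from one call:

```r
res <- run_pipeline(coh$collection, pipeline_config(), out_dir = "results_demo")
res$outcome_table[1, c("outcome", "baseline_mean", "followup_mean", "p_value")]
#>                 outcome baseline_mean followup_mean      p_value
#> 1 Monthly headache days          9.55          6.63 9.303293e-40
```

A command-line interface with `simulate | classify | aggregate | analyze |
run` subcommands is installed at
`system.file("cli", "headachediary.R", package = "headachediary")`.

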