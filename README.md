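# aidpatterns

Temporal pattern discovery in automated insulin delivery (AID) data.

People with type 1 diabetes using an AID system generate dense device logs
of three linked quantities: insulin on board (IOB, units), carbohydrates on
board (COB, grams), and interstitial glucose (IG, mmol/L). Some temporal
structure in these series is *expected* — more insulin when more
carbohydrates are eaten, higher glucose after meals. But AID systems also
adjust insulin at times and in ways that carbohydrates cannot explain,
pointing at unmeasured drivers of insulin need (activity, stress, hormones,
illness). `aidpatterns` is a toolbox for finding both kinds of structure in
such data and quantifying how often they occur across a cohort, aimed at
researchers analysing AID device logs (or building methods for them).

The core procedure, per participant:

1. **Ingest.** Irregular device logs are resampled to hourly means; a
   participant is eligible when at least 30 calendar days have at least one
   IOB, COB and IG reading in every hour.
2. **Compare.** Hourly values are grouped at several temporal granularities
   — hour of day, day of week, month of year, and learned day-clusters —
   and every unordered pair of groups is compared per variable with a Welch
   test of the difference in means. The family-wise error rate over all
   `C(G, 2)` pairs of a granularity is controlled at 5% by Bonferroni
   correction, giving per-comparison levels α = .05/276 ≈ .0002 for the 24
   hours, .0024 for the 7 weekdays, and .0008 for the 12 months. Cohen's
   *d* and achieved power accompany every comparison.
3. **Classify.** Each group pair's significance triple (IOB, COB, IG) is
   mapped to a pattern code: expected patterns E1–E3 (insulin/glucose
   changes accompanied by carbohydrate changes) and unexpected patterns
   U1–U2 (an IOB change without a COB change; an IG rise without a COB
   rise). Frequencies are tallied per participant and across the cohort.
4. **Relate & forecast.** Pattern frequencies are associated with
   demographic and device factors by Kendall τ-b, and pairwise Granger
   causality among IOB/COB/IG (lag by AIC of the target's own
   autoregression, then an F test) measures forecastability, with a
   cross-participant consistency summary. A matrix profile surfaces motifs
   and discords at day and quarter-day scales.

Because the cohort data this kind of analysis targets is access-controlled,
the package ships a synthetic cohort generator (`sim_config()`,
`simulate_cohort()`) that emulates the relevant statistical structure —
irregular sub-hourly sampling, meal-driven COB pulses, exponential IOB
kinetics, a circadian IG baseline, hourly coverage gaps, and demographics
with missingness — and supports *planting* effects with known ground-truth
pattern codes, so every stage of the pipeline is testable by recovery.

## Worked example

Simulate one participant with a planted unexpected pattern (a +3 mmol/L
glucose shift at 03:00–05:00 with no carbohydrate change), then detect and
classify it:

```r
library(aidpatterns)

cfg <- sim_config(
  n_participants = 1, days = 60, seed = 3,
  planted_effects = list(
    planted_effect("ig", "hour_of_day", 3:5, shift = 3,
                   taxonomy_truth = "U2")))

p    <- simulate_participant(cfg, 1)
grid <- resample_hourly(p$series)
eligibility_filter(grid)
#> <eligibility_report> P001: 34 qualifying days -> eligible

md   <- detect_mean_diffs(grid, "hour_of_day")  # 276 pairs x 3 variables
inst <- detect_patterns(md)
table(inst$code)
#>
#> E1 U1 U2
#> 11 19 53
```

The planted glucose shift is recovered as U2 instances at the planted
hours; the E1/U1 hits reflect the genuine diurnal meal structure the
generator also emulates (meals are concentrated in waking hours, so insulin
and carbohydrates really do differ between night and day hours). Frequency
tallies, factor associations and forecastability follow the same pattern:

```r
freq <- tally_patterns(inst, participants = "P001")

cob <- longest_covered_stretch(grid, "cob")
ig  <- longest_covered_stretch(grid, "ig")
n   <- min(length(cob), length(ig))
granger_test(cob[1:n], ig[1:n], max_lag = 12)
#> <granger_result> lag 12 (AIC), F = 2.348, p = 0.008393 -> significant at alpha 0.05
```

Carbohydrates Granger-cause glucose in this record, as the generator's
meal excursions imply they should.

`run_aid_analysis()` orchestrates the whole pipeline (simulate → ingest →
cluster → patterns → matrix profile → relate → Granger → report) from a
configuration list or YAML file and writes every stage artifact as CSV/JSON
plus a run manifest.

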