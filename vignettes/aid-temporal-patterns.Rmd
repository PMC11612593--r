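---
title: "Discovering expected and unexpected insulin-need patterns in AID data"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Discovering expected and unexpected insulin-need patterns in AID data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(aidpatterns)
```

## The problem

Automated insulin delivery (AID) systems log, at sub-hourly resolution,
insulin on board (IOB, units), carbohydrates on board (COB, grams) and
interstitial glucose (IG, mmol/L). Carbohydrate intake explains much of the
temporal variation in insulin need — but not all of it. When an AID system
repeatedly delivers more (or less) insulin at particular times without a
matching carbohydrate signal, or glucose repeatedly rises without
carbohydrates, some other driver (activity, stress, hormone cycles,
illness) is at work. This package detects such structure per participant,
classifies it as *expected* (E1–E3, explainable by carbohydrates) or
*unexpected* (U1–U2, not explainable by carbohydrates), quantifies its
frequency across a cohort, relates frequencies to demographic and device
factors, and asks whether the three series forecast one another.

Because the data the method targets is typically access-controlled, the
package includes a synthetic cohort generator with the same statistical
skeleton, and the whole pipeline is validated by planting effects with
known ground truth and recovering them.

## The detection model

All statistics operate on the **hourly grid**: per wall-clock hour, the
arithmetic mean of each variable's readings in that hour, with a coverage
flag per variable. A calendar day *qualifies* when all 24 hours have
coverage for all three variables, and a participant is *eligible* with at
least 30 qualifying days; only qualifying days feed the statistics. This is
the strictest reading of the eligibility rule ("at least one recording of
each variable every hour, for at least 30 days"): partial days are excluded
entirely, because their hourly means would over-represent whatever part of
the day happens to be covered. Day boundaries are local midnight; the
generator works in a single timezone (UTC) so local and wall-clock time
coincide.

At a granularity with $G$ groups (24 hours of day, 7 weekdays, 12 months,
or $k$ learned day-clusters), every unordered pair of groups is compared
per variable with a Welch two-sample test of the difference in hourly
means. The family of all $\binom{G}{2}$ pairs is controlled at a 5%
family-wise error rate by Bonferroni, so the per-comparison level is
$\alpha_{adj} = 0.05 / \binom{G}{2}$ — $.05/276 \approx .0002$ for hours,
$.0024$ for weekdays, $.0008$ for months (reported rounded to four
decimals; internal arithmetic is full precision). A comparison is
significant exactly when its $(1-\alpha_{adj})$ CI of the difference
excludes zero, equivalently $p < \alpha_{adj}$; the package maintains this
duality by construction. Welch (unequal variance) rather than pooled-t is
used because group sizes and variances differ by construction (months with
different day counts, unequal cluster sizes). Each comparison also carries
Cohen's $d$ (pooled, $n-1$ weighted SD) as a standardized effect size, and
the power machinery (noncentral-$t$) reports achieved power and the
per-group $n$ required for 80% power — `power_two_sample(0, ...)` is
exactly $\alpha$, and `required_n()` is definitionally the smallest $n$
reaching the target.

Cohort-level comparisons of per-participant overall means (weekday vs
weekend, winter vs summer, first vs second year, cluster vs cluster) use
the same Welch machinery at their own configured adjusted levels (defaults
.0018, .0063, .0032, .0018). These families are configurable because the
exact comparison counts behind such published thresholds are generally not
reconstructable; weekend means Saturday–Sunday and summer/winter mean
Jun–Aug / Dec–Feb (northern-hemisphere defaults).

## The pattern taxonomy

Each (granularity, group pair) yields a significance triple for
(IOB, COB, IG), each element "significantly higher", "significantly
lower", or "not significant" (orientation: later group minus earlier group
in the canonical order hour 0→23, Mon→Sun, Jan→Dec, cluster 1→k). Rules
are applied in precedence order to both orientations of the pair, so each
pair produces at most one code:

| code | IOB | COB | IG | reading |
|------|-----|-----|----|---------|
| E3 | up | up | up | all three move together |
| E1 | up | up | any | more insulin with more carbohydrates |
| E2 | any | up | up | glucose rise with more carbohydrates |
| U1 | sig. different | not sig. | any | insulin change without carbohydrates |
| U2 | any | not up | up | glucose rise not due to carbohydrates |

The rule set ships as data (`default_pattern_rules()`, YAML round-trip),
so alternative published definitions can be dropped in without code
changes. The precedence (E3 over E1/E2 over U1/U2) is a design choice:
codes could plausibly co-occur, and forcing at most one per pair makes
frequencies unambiguous. Because "frequency" can reasonably mean three
things, the tally reports all of them: raw instance counts, counts
normalized by the number of compared pairs, and the fraction of
participants with at least one instance.

## Day clustering

The "cluster" granularity groups days by shape rather than calendar
position: each qualifying day becomes a 72-vector (24 hourly means × 3
variables), z-scored per participant per variable over all qualifying-day
hours, and days are clustered by k-means (k-means++ initialization, Lloyd
iterations, best of 10 restarts by inertia, deterministic given seed). $k$
is chosen by maximum mean silhouette over 2–8, ties toward smaller $k$.
Clustering is per participant — the downstream pattern detection is per
participant, and day shapes are not comparable across people after
per-participant z-scoring. Days with any missing hour are excluded rather
than imputed, consistent with the qualifying-day rule.

## Motifs and discords

The self-join matrix profile gives, per window position, the z-normalized
Euclidean distance to the nearest non-trivial matching window (exclusion
zone $\lceil m/2 \rceil$); its minima are motifs, its maxima discords.
Default windows are $m = 24$ h (day shape) and $m = 6$ h (quarter day);
week-scale windows ($m = 168$) are available behind a flag but off by
default, as week-scale motif analysis adds little at these record lengths.
The computation is by direct evaluation of all window pairs via the Gram
matrix — exact and fast at desk scale (a 90-day record is ~2,000 windows);
approximate fast algorithms are deliberately out of scope. Windows with
standard deviation below $10^{-8}$ are floored and flagged rather than
dropped. Missing data is handled by analysing the longest contiguous fully
covered stretch: imputation would manufacture repeated shapes, i.e. fake
motifs.

## Associations and forecastability

Pattern frequencies are related to demographic factors (age, T1D duration,
HbA1c, average carbohydrates/insulin/basal, years of pump/CGM/AID use) and
device-derived factors (hours/days/months/years of data, overall mean
IOB/COB/IG) by Kendall τ-b — rank-based with tie correction, since
frequencies are heavily tied; the p-value uses the tie-adjusted normal
approximation (exact only for n ≤ 10 without ties). Sex is excluded by
default: it is categorical and, in the data this emulates, almost entirely
undisclosed. The scan is exploratory, so no multiplicity correction is
applied by default; a Benjamini–Hochberg switch exists.

Forecastability is assessed by pairwise Granger causality on level hourly
data (a differencing flag exists): the lag is chosen by minimum AIC of the
*effect's own* autoregression over 1..12 h, then the exclusion of all
lagged cause terms is F-tested at that lag. Selecting the lag on the
restricted model is deliberate: selecting on the unrestricted model is a
pretest on the very coefficients being tested and measurably inflates the
type-1 error (in our calibration at `max_lag = 12`, n = 500, the
unrestricted-selection variant rejects ~11% of independent white-noise
pairs at α = .05, the restricted-selection procedure ~4–5%). Per-direction
results are summarized across the cohort as the fraction of participants
significant, flagged *inconsistent* in the (0.2, 0.8) band — the regime in
which a direction cannot be relied on for forecasting.

## The synthetic generator

The generator emulates the data-generating structure the analysis assumes,
not glucose physiology:

* **Sampling.** Readings arrive as a Poisson process (default 12/hour,
  CGM-like); whole hours are dropped with probability 0.02, producing the
  coverage gaps the eligibility filter exists for. Record lengths default
  to 30–180 days uniform per participant, reflecting the wide per-person
  variation in donated device data.
* **Meals/COB.** Meals are Poisson (3/day) within waking hours (06–21),
  size ~ N(50, 20²) g truncated at 5 g; COB decays linearly over 3 h — the
  simplest decreasing kinetics that produce hour-scale autocorrelation.
* **IOB.** Each meal triggers a bolus of carbs/ratio (default ratio 10 g/U)
  with single-exponential decay (half-life 2 h); basal inflow (0.8 U/h)
  accumulates to its steady state under the same decay.
* **IG.** Baseline 6.5 mmol/L plus a circadian cosine (amplitude 0.5,
  peak 07:00, a dawn-phenomenon-like bump), plus per-meal excursions
  (0.03 mmol/L per gram, rising 1 h, decaying 2 h), plus sensor noise.
  mg/dL inputs are accepted and converted (18.016).
* **Noise placement.** Only IG carries sensor noise — IOB and COB are
  controller-computed quantities, not measurements. IG noise is drawn per
  hour (shared by the hour's readings) plus smaller within-hour jitter
  (half the hourly SD). This makes the SD of *hourly means* ≈ `noise_sd`,
  so a planted shift of $k \cdot$ `noise_sd` has standardized size ≈ $k$
  on the scale the detector operates on — the property the planted-recovery
  calibration relies on. Purely per-reading noise would shrink by
  $\sqrt{r}$ under hourly averaging and make planted "standardized" shifts
  mean something different at every sampling rate.
* **Plants.** A planted effect adds a constant shift to one variable in
  chosen slots of one granularity and records the intended taxonomy code.
  For shifts specified in standardized units, `shift_for_effect_size()`
  estimates the variable's hourly-mean SD from one unplanted reference
  simulation of the same configuration (a fixed scale estimate, computed
  before any detection).
* **Demographics.** Realistic marginals (HbA1c centred at 46 mmol/mol,
  i.e. a well-controlled, technology-experienced cohort) with configurable
  per-field missingness; sex is missing with probability 0.9 by default,
  mirroring how rarely it is disclosed in donated datasets.

What the generator does **not** emulate: glucose–insulin feedback (no
ODE/physiological model), exercise/stress/illness covariates, device
dialect quirks, timezone travel, or sensor artefacts (compression lows,
calibration jumps). Consequently, passing recovery tests shows the
*pipeline* is correct and calibrated — it does not show that real data
meets the tests' assumptions (normality-ish hourly means, within-hour
exchangeability, missingness unrelated to values).

Determinism: the cohort is a pure function of the configuration. Each
participant draws from a sub-seed mixed from the cohort seed and the
participant index, so extending a cohort never re-randomizes earlier
participants.

## Calibration experiments and problem sizes

The validation suite (and `scripts/acceptance.R`) runs, at sizes chosen to
make Monte-Carlo error small relative to the bands being checked:

* **Null FWER**: 200 independent null participants (60 days each,
  meal-free, circadian-free, IG noise only), fraction with ≥ 1 detected
  hour-of-day pattern ≤ 0.05 + 3 MC SE. Meals and the circadian term are
  removed because they create *real* hour-of-day differences — with them, a
  rejection is a discovery, not an error.
* **Planted recovery**: 50 participants × 90 days with standardized-size-2
  plants (E1 at 14:00–16:00 via joint IOB+COB shifts, U2 at 03:00–05:00
  via an IG shift, meals spread over all 24 h so unplanted hours are
  exchangeable); ≥ 95% of plants recovered at the Bonferroni-adjusted α.
* **Oracle equivalence**: τ-b vs an exhaustive pair-counting oracle on 100
  tied vectors (exact), and the matrix profile vs a brute-force double-loop
  recomputation on a 500-point AR(1) series (≤ 1e-9).
* **Granger calibration**: size on 500 white-noise pairs (length 500),
  power ≥ 0.95 on 100 one-lag-coupled pairs (length 2000, coefficient
  0.8), reverse direction at size level.
* **Clustering recovery**: planted day archetypes at 4× within-archetype
  noise, ARI ≥ 0.9 and correct $k$ selection.

## Known limitations

* The taxonomy defaults encode the two well-documented exemplars (E-codes
  as carbohydrate-explained insulin/glucose increases, U2 as a glucose
  rise without carbohydrates) plus natural completions; published rule
  tables vary, which is why rules are editable data.
* Hourly means within a group are treated as exchangeable; meal-driven
  autocorrelation between adjacent hours on the same day mildly violates
  this. The Bonferroni family and the conservative qualifying-day rule
  absorb most of the slack (the null calibration stays below its band),
  but the tests are not exact under strong autocorrelation.
* Granger causality here is bivariate and linear, on levels by default;
  it measures linear predictive improvement, not physiological causation.
* Normalized pattern frequencies divide by compared pairs, which differs
  across participants for the cluster granularity (different $k$, group
  sizes); the per-participant counts and participant fractions are the
  robust cross-participant summaries.
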