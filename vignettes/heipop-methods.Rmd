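---
title: "Methods: population-ratio HEI-2015 scoring by food outlet"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: population-ratio HEI-2015 scoring by food outlet}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(heipop)
```

## The estimator

The HEI-2015 evaluates a mix of foods against the 2015–2020 Dietary
Guidelines through 13 density-based components: nine adequacy components
(total fruits, whole fruits, total vegetables, greens and beans, whole
grains, dairy, total protein foods, seafood and plant proteins, and the
fatty-acid ratio) where a higher density earns more points, and four
moderation components (refined grains, sodium, added sugars, saturated
fats) where a lower density does. Component maxima (5 or 10 points) sum to
100.

`heipop` estimates group-level scores with the **population ratio method**:
all item amounts and energy in the group are summed with each item weighted
by its respondent's day-1 dietary weight, and each component's density is
the ratio of weighted totals,

$$D_c \;=\; \frac{\sum_i w_i\, x_{ci}}{\sum_i w_i\, e_i / 1000},$$

rather than a mean of per-person ratios. The two estimators differ whenever
energy varies across people — the mean-of-ratios estimator up-weights
low-energy reporters — and the package's tests exhibit the inequality on a
two-person example. Added sugars and saturated fat are expressed as percent
of energy using fixed conversions of 16 kcal per teaspoon-equivalent and
9 kcal per gram; sodium as grams per 1000 kcal; the fatty-acid component as
the dimensionless (MUFA+PUFA)/SFA ratio.

Scoring is piecewise linear between two cut-points per component: full
points at or beyond the full-score density, zero at or beyond the
zero-score density, linear interpolation in between. The cut-points ship as
an editable CSV (`inst/extdata/hei2015_standards.csv`) transcribed from the
HEI-2015 technical specification, so synthetic standards can be substituted
in tests and any future revision is a data edit, not a code change.
Degenerate fatty-acid denominators follow the continuity of the clamp: zero
saturated fat with positive unsaturated fat gives an infinite ratio and full
points; zero of both gives zero points.

Letter grades map percent-of-maximum to A (≥ 90) through D (60–69.99), with
F covering everything below 60: the conventional component wording labels
only 50–59% as "F" and leaves lower percentages unnamed, so the package
closes the scale downward.

## Outlet stratification

Each item's source-of-food label (or numeric code) maps through an editable
table into seven mutually exclusive detailed categories — store, school,
full-service restaurant, quick-service restaurant, community food program,
homegrown, other — of which the first four are the analytic outlets;
community food programs, homegrown food and miscellaneous sources are too
sparse for outlet-level comparison and enter only the all-outlets
aggregate. Unknown labels are an error, never silently bucketed, and labels
absent from the published option lists (for example "Child care center")
deliberately map to `other`. The numeric codes in the shipped table come
from the survey's dietary documentation and live in data, not code, because
codes drift across cycles.

## Survey inference

NHANES publishes masked stratum/PSU design variables but no replicate
weights, so the package constructs balanced repeated replication (BRR)
weights itself on the two-PSU-per-stratum design: in each replicate one PSU
per stratum is inflated by $2-k$ and the other shrunk to $k$, with Fay
coefficient $k = 0.3$ (factors 1.7/0.3; $k=0$ recovers classic BRR's 2/0).
Half-sample selection follows the columns of a Sylvester Hadamard matrix of
the smallest power-of-two order at least `n_strata + 1`; the all-ones column
is dropped so every stratum's selection column is balanced and the replicate
weights average back to the base weights. Strata with more than two PSUs are
split into pseudo-pairs by PSU order (logged); single-PSU strata are an
error. For any statistic $\hat\theta$,

$$\widehat{SE} = \sqrt{\frac{1}{R(1-k)^2}\sum_{r=1}^{R}
  (\hat\theta_r - \hat\theta)^2},$$

which the tests verify against the closed-form stratified variance
estimator for linear statistics.

Pairwise outlet contrasts form the difference of the two outlet scores
within each replicate and refer the t statistic to $\#PSU - \#strata$
degrees of freedom, the standard complex-survey rule. Raw p-values are
compared against 0.05 with no multiplicity adjustment, matching common
reporting practice for these comparisons; a Bonferroni correction is a
one-line wrapper if wanted. The cycle trend regresses the *cycle-level*
population-ratio score on the cycle index 0, 1, … by ordinary least
squares, recomputing the slope with replicate-$r$ weights in every cycle
(each cycle keeps its own replicate set, built with a common Hadamard order
so replicate counts agree); an alternative reading — regressing person- or
item-level data on time — is defensible but was not chosen because the
scores being compared are themselves cycle-level population-ratio
statistics. The trend's degrees of freedom sum $\#PSU - \#strata$ over
cycles.

## The synthetic generator

`generate_recalls()` emulates the structure the pipeline assumes:
respondents assigned round-robin to strata with two PSUs each, lognormal
day-1 weights (meanlog 0, sdlog 0.3 by default — modest dispersion typical
of post-stratified dietary weights), uniform ages 2–85, Poisson item counts
(mean 15 items per respondent-day, a realistic recall length) allocated
across outlets by an optionally age-dependent mixture (default: 70% store,
15% quick-service, 8% full-service, 5% school, 2% other, in line with
observed calorie sourcing), outlet-specific lognormal item energies, and
component amounts

$$x_{ci} = \frac{e_i}{1000}\, d_{c}^{\text{true}}\, \eta_{ci},
  \qquad \eta \sim \Gamma(\text{cv}^{-2}, \text{cv}^{-2}),$$

multiplicative mean-one gamma noise (cv 0.3 by default). Because the noise
has mean one and enters multiplicatively, the population-ratio estimator is
consistent for the configured density — the ratio of weighted means — so
`expected_scores()` obtains the exact large-sample truth by scoring the
configured densities directly, and at `cv = 0` the pipeline reproduces them
exactly. Target component scores are inverted through the (linear) scoring
map to densities, which makes profiles easy to state in score space.

The packaged default profiles place expected totals near the published
2017–2018 pattern (schools ≈ 65, stores ≈ 62, full-service ≈ 51,
quick-service ≈ 39) for demonstration; they are a convenient ground truth,
not a reproduction of survey estimates. The generator does not model food
co-occurrence, seasonality, intra-person day-to-day correlation, or
realistic per-food portion distributions — so passing tests demonstrate the
estimator's and variance machinery's correctness under a known design, not
agreement with real NHANES/FPED data, which require the external microdata
files read by `read_respondents()`/`read_food_items()` (CSV or SAS
transport) and a per-cycle column dictionary.

## Numerical and design choices

* Missing component cells are imputed to zero with a reported count: recall
  files encode "none consumed" as absence, and zero-imputation preserves
  the additivity the ratio estimator relies on. Rows whose every referenced
  source cell is missing are counted as unlinked and reported.
* The per-cycle dictionary's source field accepts small linear expressions
  (`F_TOTAL-F_JUICE`, sums with scalings), since derived components such as
  whole fruits and the legume additions into vegetables and protein are not
  expressible as a 1:1 column rename.
* Zero group energy is an error naming the group rather than a NaN score.
* Scores are reported to two decimals (round-half-even) in tables; internal
  arithmetic is full precision. Radar plots use full precision and a fixed
  canonical axis order (total fruits → saturated fats) so patterns are
  comparable across plots.
* Contrast/trend statistics with zero BRR variance return p = 1 when the
  estimate is also zero (identical groups) and p = 0 otherwise.

## Problem sizes used in the shipped checks

The test suite exercises parameter recovery on one generated population of
2000 respondents (≈ 30,000 items), trend recovery on eight 400-respondent
cycles with a 1.5-point-per-cycle injected slope, and the contrast test's
size on 500 null populations of 240 respondents in 12 strata (measured
rejection rate 0.058 at nominal 0.05). These sizes give Monte-Carlo error
comfortably inside the asserted tolerances while keeping the suite fast.

## Known limitations

* Real-data mode expects the user to supply NHANES + FPED/MPED files and to
  verify the dictionary's column expressions against each cycle's
  documentation; the shipped 2017–2018 dictionary rows are a template.
* BRR pseudo-pairing of >2-PSU strata is a pragmatic fallback; certainty
  about the agency's internal pairing is not possible from public files.
* No usual-intake (measurement-error) modelling: estimates describe the
  mix of foods reported on one day, not long-run diets.
* Day-2 recalls and per-person score distributions are out of scope; the
  per-person mean-ratio estimator appears only as a comparison in tests.
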