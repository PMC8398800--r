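# heipop

Population-ratio HEI-2015 scoring of foods by food outlet, with
replicate-weight survey inference.

## What it is for

The Healthy Eating Index 2015 (HEI-2015) measures how well a *mix of foods*
aligns with the 2015–2020 Dietary Guidelines for Americans. Because it is
density-based — every component is expressed relative to energy — it can
score any set of foods, not just a person's whole diet. `heipop` implements
the recommended group-level estimator, the **population ratio method**, and
applies it to 24-hour dietary recall microdata stratified by the *outlet*
where each food was obtained (stores, schools, full-service and
quick-service restaurants). It is aimed at nutrition epidemiologists working
with NHANES/What We Eat in America style recall files linked to food-pattern
equivalents (FPED/MPED), and at anyone who needs a tested HEI-2015 engine
for arbitrary weighted food mixes.

For a group \(g\) with items \(i\), respondent day-1 weights \(w_i\), energy
\(e_i\) and component amounts \(x_{ci}\), the population-ratio density of
component \(c\) is

    D_c = (Σ_i w_i x_ci) / (Σ_i w_i e_i / 1000)

(percent of energy for added sugars at 16 kcal/tsp-eq and saturated fat at
9 kcal/g; (MUFA+PUFA)/SFA for the fatty-acid ratio). Each density is scored
piecewise-linearly between a zero-score and a full-score cut-point; the 13
component scores (9 adequacy, 4 moderation) sum to a 0–100 total. Variance
of any group statistic comes from balanced repeated replication (BRR) with a
Fay coefficient of 0.3 on the two-PSU-per-stratum design; outlet differences
are tested as replicate-wise contrasts and changes across survey cycles as a
BRR-weighted linear trend.

A synthetic recall-data generator with analytically known ground truth
(mean-one multiplicative noise, so the population-ratio estimator converges
to the configured density) stands in for the survey microdata, which cannot
be redistributed.

## Worked example

```r
library(heipop)

cfg <- synthetic_config(n_respondents = 2000)   # NHANES-like population
pop <- generate_recalls(cfg, seed = 42)
kept <- apply_eligibility_filters(pop$respondents, pop$items)

rw  <- build_replicates(kept$respondents, fay_k = 0.3)
fit <- hei(kept$items, kept$respondents, outlet = "school",
           replicates = rw)
fit
#> HEI-2015 population-ratio score
#>   group : school
#>   items : 1536 from 1064 respondents
#>   total : 65.01 / 100  (grade D)
#>   BRR SE of total: 0.339
```

The total of 65.01 says the mix of foods obtained from school cafeterias
earns about 65 of 100 points — a "D": well short of full alignment with the
guidelines, but (as `summary(fit)` shows component by component) with full
marks for dairy and near-full marks for fruits, and most of the shortfall in
vegetables, protein foods and the fatty-acid ratio. `plot(fit)` draws the
13-axis radar plot of the component pattern, and

```r
store <- hei(kept$items, kept$respondents, outlet = "store")
radar_plot(list(fit, store))
```

overlays outlets for comparison. Outlet contrasts and cycle trends use the
replicate machinery directly; see the vignette (`vignettes/heipop-methods.Rmd`)
for complete examples.

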