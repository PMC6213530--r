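---
title: "Methods: database construction, free-sugar classification and habitual intake"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: database construction, free-sugar classification and habitual intake}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(starchsugar)
```

## The problem

National food-composition tables rarely analyse every food for every
nutrient. For starch and the individual mono- and disaccharides, a
typical situation is that ~40% of items carry analysed values and the
rest must be filled before any population intake can be computed.
This package implements the full path from such a table to stratified
intake estimates: value assignment with provenance, classification of
total sugar into free and naturally occurring sugar, intake
calculation from weighed dietary records, and correction of the
intake distribution for day-to-day variation.

## Value assignment

All contents are g/100 g edible portion. `NA` is an explicit MISSING
sentinel; `0` is always a measured or assigned value. Two derived
quantities anchor the cascade:

* available carbohydrate `= (100 − water − protein − lipid − ash) −
  dietary fiber`, clamped at 0 with a warning when proximate rounding
  makes it negative (magnitudes below 1e-9 are snapped to zero
  silently — they are pure binary representation error of one-decimal
  table values);
* dry weight `= 100 − water`, the basis for transferring values
  between forms of a food.

The cascade runs in a fixed, configurable order: (1) analytical
values already in the table; (2) an all-zero profile where available
carbohydrate is 0 (nothing to distribute); (3) literature values,
aggregated per food and component by median (default) or mean —
median is the default because it is the more robust convention for
starch aggregation, with a per-food override; (4) the same food in
another form and (5) a similar food of the same family or order, both
by the identical dry-weight ratio `value × dry_target / dry_ref`;
(6) recipe calculation `Σ(content_i × weight_i) / yield`; (7) overseas
tables, one country per item by the fixed priority US > UK > AU
(import statistics, the criterion a table compiler would use first,
are not computable here, so a fixed priority stands in; it is
configurable), with UK disaccharides multiplied by 0.95 because UK
tables express them as monosaccharide equivalents.

Items no step can resolve receive an all-zero profile, are labelled
`ZERO_FALLBACK` and are reported in an exceptions list — zeros keep
population totals conservative and the list keeps the gap visible.
Every imputed component is capped at available carbohydrate (a table
invariant; analytical values are exempt and only audited, with a
0.5 g/100 g tolerance for starch + total sugar vs. available
carbohydrate, the typical rounding slack of printed tables). A
reference item with dry weight 0 aborts that step for that item and
the cascade moves on rather than failing the run.

Starch uses the same source steps and closes differently: remaining
items with available carbohydrate > 0 get
`starch = max(0, available carbohydrate − total sugar)`
(`CARB_DIFFERENCE`); the rest get 0. Literature components not
reported by any study are taken as 0 when at least one component is
reported — analytical papers report what they detect, so an absent
component is read as a non-detect rather than MISSING.

Two structural properties are enforced and tested: the cascade is
deterministic (same inputs, same config, byte-identical output) and
step-monotone (an item assigned at step *k* is never overwritten
later).

## Free-sugar classification

Free sugar follows the WHO definition: sugars added by the
manufacturer, cook or consumer, plus sugars naturally present in
honey, syrups and fruit juice. The split is an ordered rule tree,
first match wins; predicates evaluate food group, then form, then a
name pattern — in that order because group membership and form are
reproducible while name matching is fragile. The shipped default
(`inst/extdata/free_sugar_rules.json`):

1. sugars and jams, confectionaries, sugar-sweetened beverages, fruit
   juices → ALL_FREE;
2. raw or cooked fruits and vegetables → NONE_FREE;
3. plain dairy, staple grains, noodle, potatoes, pulses, mushrooms,
   seaweeds, fish, meats, eggs, fat and oil, vegetable juices, tea and
   coffee, alcoholic beverages → NONE_FREE;
4. seasonings → FRACTION(0.5) — sweetened sauces mix added sugar with
   sugars from ferments, and 50% is the convention of published
   stepwise added-sugar methods when a split cannot be derived;
5. bread/other grain products/other foods with sweet-indicating names
   → ALL_FREE;
6. remaining composites → FROM_RECIPE, summing ingredient free sugar
   through the recipe formula, clamped to the item's own total sugar.

Items matching no rule (or FROM_RECIPE without a recipe) take a
configurable default fraction (0.5) and are flagged for review.
Conservation — free + naturally occurring = total sugar — holds
exactly (to one float ulp) for every item and propagates to per-day
intakes.

## Intake estimation

Records store net consumed amounts (leftovers already subtracted) in
grams of edible portion; intake is `amount/100 × content` summed over
a person-day, averaged over recorded days. Energy adjustment uses
4 kcal/g (Atwater) for starch and all sugars, configurable. WHO
adherence applies closed thresholds (a person at exactly 10.0 %E
counts as ≥10 %E), matching the "excessive intake" reading of the
recommendation. Sex comparisons use the equal-variance two-sample
t-test for means and Pearson's chi-square without continuity
correction for prevalences, two-sided.

Food-group contributions are the mean of per-person ratios (each
person's group share of their own total intake), not the ratio of
population means — "mean value of the contribution" is read as
mean-of-ratios; the alternative would weight heavy consumers more.
Persons with zero intake of the nutrient are excluded and logged.
Rows sum to 100 exactly; a display threshold (default 7%) collapses
minor groups into "others".

## Habitual intake (best-power method)

Short records mix stable between-person differences with day-to-day
noise: the variance of k-day person means overestimates the
between-person variance by σ²_w/k on the transformed scale. The
method here is a reference reimplementation — the software used in
the original analyses is not publicly specified — so every choice is
explicit and configurable:

* **Transform family**: one-parameter power transform
  `(x^λ − 1)/λ`, log at λ = 0.
* **λ selection**: grid −2…2, step 0.01, minimising the absolute
  sample skewness of pooled person-day values; ties break to the λ
  closest to 1; constant data returns 1. Zeros are handled by adding
  half the smallest positive value to all observations (subtracted
  after back-transformation, clamped at 0).
* **Variance decomposition**: one-way random-effects ANOVA with the
  unbalanced-data coefficient `n₀ = (N − Σnᵢ²/N)/(k − 1)`;
  σ²_w = MSW, σ²_b = max(0, (MSB − MSW)/n₀).
* **Shrinkage**: person means move toward the grand mean by
  `√(σ²_b/(σ²_b + σ²_w/nᵢ))`, so the variance of the shrunk values
  equals σ²_b in expectation.
* **Back-transform**: second-order correction
  `x̂ = g⁻¹(t) + ½ g⁻¹″(t) σ²_w`, because a usual intake is the mean
  of daily intakes, which average over day-to-day noise of variance
  σ²_w on the transformed scale. At λ = 0 this reproduces the
  lognormal mean `exp(t + σ²_w/2)` to second order. The correction
  variance is a deliberate design decision; alternatives (no
  correction, shrink-residual variance) change estimates by O(σ⁴).

Estimation runs independently per nutrient and per age-sex stratum;
strata recorded on a single day (toddlers) are skipped — within-person
variance is not estimable from one day — and their adherence
statistics fall back to observed single-day values, which widens the
apparent distribution and should be read with caution.

## The synthetic world

The generator emulates the survey's published conditions and is not
adjusted afterwards: ~2222 items with 39.6% analysed; stratum sample
sizes 183/185, 186/190, 435/480, 196/196 (male/female); 1/3/3/4
recording days; stratum mean starch targets from the published intake
table (e.g., adult men 203.4 g/day); EI/EER 1.22/1.23 for toddlers
and 1.00 elsewhere. Daily starch is lognormal with between-person
CV 0.25 and within-person CV 0.35 — typical nutrition-survey
magnitudes, and lognormal so the power-transform stage is exercised
away from λ = 1. Food amounts are sampled from group-weighted foods
and rescaled so each day's computed starch equals the drawn total;
other nutrients ride along with the food pattern and are therefore
*not* individually calibrated. The synthetic EER table is the
realized stratum mean energy divided by the stratum EI/EER target — a
labelled stand-in for the external dietary-reference table, which is
not redistributable.

Ground truth for derived items is defined *downstream* of the
one-decimal rounding of emitted values (a reference is rounded first,
then the target's truth is computed by the exact cascade formula), so
formula-resolvable sources must reproduce truth to 1e-9 — a
construction oracle. What a green recovery test does **not**
establish: that real similar-food or recipe imputation is unbiased
(the generator builds "similar" items by the very ratio the cascade
assumes), nor that the intake magnitudes of any real population are
reproduced — the published intake and contribution tables cannot be
reproduced because the underlying records are not deposited; they
serve only as calibration targets checked in sampling distribution.

## Numerical choices and limitations

* Percentages print with half-up rounding (1e-9 tie tolerance);
  base R's round-to-even would disagree with published tables at
  exact ties.
* Degenerate sex comparisons (zero variance in both groups, equal
  means) return p = 1 rather than NaN.
* Oligosaccharides, sugar alcohols, cooking retention beyond the
  dry-weight ratio, misreporting correction beyond the EI/EER screen,
  seasonality and episodic-consumption (two-part) usual-intake models
  are out of scope.
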