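# starchsugar

Tools for estimating starch and sugar intake in populations whose
national food-composition table reports saccharide values for only a
fraction of its items — the situation of the Japanese standard tables,
where roughly 40% of ~2200 foods carry analysed starch and saccharide
(glucose, fructose, galactose, sucrose, maltose, lactose, trehalose)
contents and no total, free or naturally occurring sugar is tabulated.

The package is aimed at nutrition epidemiologists who need to go from
a partially analysed composition table plus weighed dietary records to
population intake estimates. It implements four stages:

1. **Database construction** (`assign_saccharides()`,
   `assign_starch()`): a stepwise value-assignment cascade fills the
   missing values — analytical values first, then zero assignment for
   foods without available carbohydrate, literature values
   (median/mean aggregation), dry-weight scaling from the same food in
   another form, dry-weight scaling from similar foods
   (`content_target = content_ref × dry_target / dry_ref`), recipe
   calculation (`Σ content_i × weight_i / yield`), and conversion from
   overseas tables (UK disaccharides are monosaccharide equivalents,
   × 0.95). Starch closes with carbohydrate difference
   (`max(0, available carbohydrate − total sugar)`) and a zero step.
   Every value carries provenance; `provenance_summary()` audits the
   result. Available carbohydrate is carbohydrate by difference minus
   dietary fiber: `(100 − water − protein − lipid − ash) − fiber`.

2. **Free-sugar classification** (`classify_free_sugar()`): an ordered
   rule tree splits total sugar into free sugar (added by
   manufacturer, cook or consumer, plus sugars in honey, syrups and
   fruit juice — the WHO definition) and naturally occurring sugar
   (`total − free`), with outcomes NONE_FREE / ALL_FREE / FRACTION(p)
   / FROM_RECIPE. The tree is data (JSON), not code.

3. **Intake estimation** (`compute_daily_intake()`, `person_intake()`,
   `who_adherence()`, `compare_sexes()`, `contribution_by_group()`):
   per person-day nutrient intakes from records
   (`amount/100 × content`), energy adjustment
   (`%E = g × 4 kcal/g ÷ energy × 100`), EI/EER misreporting screens,
   prevalence of free-sugar intake ≥10%E and ≥5%E (closed thresholds),
   equal-variance t and chi-square sex comparisons, and mean-of-ratios
   food-group source attribution over 24 groups.

4. **Habitual intake** (`fit_habitual()`, `habitual_estimates()`): the
   best-power method removes day-to-day variance from 3–4-day records:
   a grid-searched power transform `(x^λ − 1)/λ` (log at λ = 0) picked
   to minimise skewness, a one-way random-effects ANOVA
   (`σ²_w = MSW`, `σ²_b = max(0, (MSB − MSW)/n₀)`), shrinkage of
   person means toward the grand mean by
   `√(σ²_b/(σ²_b + σ²_w/nᵢ))`, and a bias-corrected back-transform.

A synthetic-data generator (`generate_composition_table()`,
`generate_dietary_records()`) produces masked composition tables whose
ground truth the cascade must recover exactly, and multi-day records
with known habitual intakes, so the whole pipeline is testable without
restricted survey data.

## Worked example

```r
library(starchsugar)

cfg <- generator_config(seed = 42, n_items = 300,
  n_persons = list(toddler = c(male = 20, female = 20),
                   preschool = c(male = 20, female = 20),
                   schoolchild = c(male = 20, female = 20),
                   adult = c(male = 40, female = 40)))
syn <- generate_composition_table(cfg)
db <- assign_saccharides(syn$table, syn$literature, syn$links,
                         syn$recipes, syn$overseas)
db <- assign_starch(db, syn$literature, syn$links, syn$recipes,
                    syn$overseas)
db <- classify_free_sugar(db, recipes = syn$recipes)
provenance_summary(db)
#>                 source   n  pct
#> 1     STFCJ_ANALYTICAL 119 39.7
#> 2           LITERATURE  18  6.0
#> 3 SAME_FOOD_OTHER_FORM  27  9.0
#> 4         SIMILAR_FOOD  37 12.3
#> 5               RECIPE  27  9.0
#> 6          OVERSEAS_DB  36 12.0
#> 7      CARB_DIFFERENCE   0  0.0
#> 8        ZERO_FALLBACK  36 12.0
```

119 of 300 items (39.7%) came with analytical profiles; the cascade
resolved the rest from literature, form/similar-food scaling, recipes
and overseas tables, falling back to zero for 36 items (12%, reported
in `attr(db, "exceptions")`).

```r
rec <- generate_dietary_records(cfg, db)
daily <- compute_daily_intake(rec$records, db)
intakes <- person_intake(daily, rec$persons)
adult_men <- subset(intakes, age_group == "adult" & sex == "male")
mean(adult_men$starch); mean(adult_men$starch_pctE); mean(adult_men$ei_eer)
#> 203.4   33.9   1.00
who_adherence(adult_men$free_sugar_pctE)
#> $ge10 5.0   $ge5 32.5
```

Adult men average 203.4 g/day starch (33.9% of energy) with EI/EER
1.00 — the generator's stated calibration — and 5.0% of them get at
least 10% of energy from free sugar.

```r
sel <- daily$person_id %in% adult_men$person_id
m <- fit_habitual(daily$starch[sel], daily$person_id[sel])
m
#> Habitual-intake model (best-power method)
#>   lambda      -0.04
#>   sigma2_b    0.0433341
#>   sigma2_w    0.0788967
#>   grand mean  4.71082 (transformed scale)
#>   persons     40
sd(adult_men$starch); sd(habitual_estimates(m)$habitual)
#> 67.2   56.0
```

The raw 4-day means spread 67.2 g/day; removing within-person
variance shrinks the habitual SD to 56.0 g/day — the usual-intake
distribution is narrower than short-term records suggest.

## Command line

```sh
Rscript inst/cli/starchsugar-cli.R simulate --outdir fixtures --seed 42
Rscript inst/cli/starchsugar-cli.R run-all \
  --composition fixtures/composition.csv --persons fixtures/persons.csv \
  --records fixtures/records.csv --literature fixtures/literature.csv \
  --links fixtures/links.csv --recipes fixtures/recipes.csv \
  --overseas fixtures/overseas.csv --out report.json
```

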