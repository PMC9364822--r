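# fsamnps

Nutrient profiling and diet-quality epidemiology in R: the modified Food
Standards Agency Nutrient Profiling System (FSAm-NPS — the algorithm
underlying the Nutri-Score front-of-pack label), the individual-level
energy-weighted FSAm-NPS Dietary Index, and the cohort association
pipeline that relates the index to cardiovascular risk factors.

The package is aimed at nutritional epidemiologists working with
food-frequency questionnaires (FFQs): it scores foods from per-100 g/ml
composition, converts FFQ frequency reports into daily intakes, aggregates
food scores into a per-participant dietary index, and fits tiered linear
regressions of risk factors on the index with cluster-robust variance. A
synthetic cohort generator with planted effects makes the entire pipeline
testable end to end without access-restricted cohort data.

## The score and the index

Each food earns "negative" points A (0–10 each for energy, sugars,
saturated fat and sodium per 100 g/ml; 0–40 in total) and "positive"
points C (0–5 each for fiber, protein and the fruit/vegetable/legume/
nut/oil percentage; 0–15 in total for general foods). Points come from
fixed band tables (the 2015 HCSP grids, bundled as versioned config); a
value earns the points of the highest threshold it *strictly* exceeds.
The total score is

    FSAm-NPS = A − C  ∈  [−15, 40]        (general foods)

with lower scores indicating healthier foods. Category exceptions:
beverages use dedicated energy/sugar/fvln grids, added fats score
saturated fat on the saturated-fat-to-total-lipid ratio, and cheese always
keeps its protein points; otherwise protein points are discarded when
A ≥ 11 and the fvln points are below their maximum.

The individual-level index is the energy-weighted mean over all consumed
items *i*,

    DI = Σᵢ FSᵢ · Eᵢ / Σᵢ Eᵢ ,

where Eᵢ is the mean daily energy contributed by item *i*; higher DI means
lower overall dietary quality. Cohort analyses code the DI (or its 1-year
change) as cohort tertiles or as a continuous term, and fit OLS with
cluster-robust (Stata-convention) sandwich variance at three adjustment
tiers (crude; + sociodemographics, BMI, energy, activity; + medications,
centre size, intervention arm).

## Worked example

Score a handful of familiar foods:

```r
library(fsamnps)
foods <- data.frame(
  item_id  = c("wholegrain_bread", "cola", "manchego", "virgin_olive_oil", "lentils"),
  category = c("general", "beverage", "cheese", "added_fat", "general"),
  energy   = c(1000, 180, 1700, 3700, 450),  sugars  = c(3, 10.5, 0.5, 0, 1.8),
  satfat   = c(0.4, 0, 21, 14, 0.1),         total_fat = c(1.5, 0, 34, 100, 0.5),
  sodium   = c(500, 10, 700, 1, 2),          fiber   = c(7, 0, 0, 0, 8),
  protein  = c(9, 0, 25, 0, 9),              fvln_pct = c(0, 0, 0, 100, 100))
score_foods(foods)[, c("item_id", "a_total", "c_total", "protein_counted", "total")]
#>            item_id a_total c_total protein_counted total
#> 1 wholegrain_bread       7      10            TRUE    -3
#> 2             cola      13       0           FALSE    13
#> 3         manchego      22       5            TRUE    17
#> 4 virgin_olive_oil      11       5            TRUE     6
#> 5          lentils       1      15            TRUE   -14
```

Lentils sit near the −15 floor (maximal fiber/protein/fvln points, almost
no A points); cola loses its (zero) protein points because its A subtotal
of 13 crosses the cap with no fvln points; cheese keeps protein points by
the cheese exception.

A complete simulated analysis — generate a cohort, run the pipeline, fit a
change-on-change model:

```r
sim <- simulate_cohort(sim_config(n_participants = 500, seed = 42))
nps_lm("glucose_change", sim$analysis_data, exposure = "tertile",
       tier = "full", analysis = "prospective")
#> FSAm-NPS DI prospective model (full, tertile exposure)
#> outcome: glucose_change   n = 480, clusters = 23, R^2 x 100 = 6.58
#>   factor(di_change_tertile)2    2.454 (-1.095, 6.003)  p = 0.166
#>   factor(di_change_tertile)3    3.553 (0.098, 7.008)  p = 0.0444
#>   P-trend = 0.0441
```

Participants whose index change fell in the worst tertile (T3) show a
3.6 mg/dL greater 1-year glucose increase than T1, with a significant
monotone trend — the generator planted a positive glucose effect
(0.35 mg/dL per index unit), so this is the expected signal; n = 480
because 20 of 500 participants were injected with the exclusion-rule
violations the pipeline is required to catch. `run_table2()` /
`run_table3()` assemble the full 8-outcome × 3-tier grids, and
`descriptive_table()` builds tertile-stratified baseline summaries.

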