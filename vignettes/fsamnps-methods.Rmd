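---
title: "Methods: FSAm-NPS scoring, the energy-weighted dietary index, and the cohort analysis pipeline"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: FSAm-NPS scoring, the energy-weighted dietary index, and the cohort analysis pipeline}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fsamnps)
```

This vignette is the package's account of its science: the scoring model
and its conventions, the index and analysis models, what the synthetic
generator does and does not emulate, and the choices made where the design
was genuinely open.

## 1. The food-level score

The modified FSA nutrient profiling system assigns each food or beverage,
from its composition per 100 g (100 ml for beverages), "negative" points
A for energy (kJ), sugars (g), saturated fat (g) and sodium (mg) — 0–10
each — and "positive" points C for fiber (g, AOAC), protein (g) and the
percentage of fruit, vegetables, legumes, nuts and rapeseed/walnut/olive
oil (fvln) — 0–5 each (fvln 0–10 for beverages). The total is `A − C`,
spanning −15 (healthiest) to 40 for general foods.

Points come from the 2015 HCSP band tables, shipped both in code
(`nps_bands()`) and as a YAML file
(`inst/extdata/bands_hcsp2015.yaml`) so the grids are auditable and
swappable without touching the engine. Conventions that matter at
boundaries:

* **Strict thresholds.** A value earns the points of the highest
  threshold it *strictly* exceeds, matching the published grids
  ("> 335 kJ earns 1 point"). A food at exactly 335 kJ earns 0. Boundary
  foods differ between the strict and non-strict conventions, so this is
  asserted in tests (e.g. 5 g saturated fat exceeds the 1–4 g thresholds
  only and earns 4 points).
* **Protein cap.** Protein points are discarded when `A ≥ 11`, unless
  the fvln points are at their category maximum or the food is cheese
  (the cheese exception of the French adaptation). The cap value 11 is
  part of the band configuration.
* **Category exceptions.** Beverages use dedicated energy, sugar and
  fvln grids (any energy above 0 scores; fvln reaches 10 points). Added
  fats score the saturated-fat component on the ratio
  `100 · satfat / total_fat` using a dedicated percentage grid; an
  added fat with zero total fat scores 0 ratio points and is flagged
  rather than erroring.
* **Units.** The engine scores kJ and sodium mg; loaders convert
  kcal (× 4.184) and salt (g × 1000 / 2.5) on input, because FFQ
  composition databases are commonly kcal- and salt-denominated.
* **Sign convention.** The published description of the subtraction is
  ambiguous about orientation; the package uses `total = A − C`, the only
  orientation consistent with the stated −15..40 range.

`score_extremes()` audits the attainable range by exhaustively scoring
the grid of per-component extremes (0 and just above every threshold,
~2.1 million profiles for a general food); under the default tables it
attains exactly −15 and 40 with subtotal caps 15 and 40. The bounds are
asserted for general foods only: a beverage's fvln grid reaches 10
points, so the beverage minimum is lower by construction, and no range
claim is made for it.

The olive-oil sensitivity analysis (`reclassify_olive_oil()`) sets the
total of designated olive-oil items to −8, the healthiest value used for
fruit, vegetables and legumes, leaving all other scores untouched. Under
the default bands any real olive-oil composition scores well above −8, so
for the energy-weighted index the reclassification can only lower an
oil consumer's index.

## 2. From FFQ reports to intakes

FFQ responses are ordinal frequency categories 1–9 (never … more than
six times a day) per item and timepoint. The published instrument pins
only the endpoint categories; the interior servings-per-day values are
the usual Willett-style midpoints (never = 0, 1–3/month = 2/30,
1/week = 1/7, 2–4/week = 3/7, 5–6/week = 5.5/7, 1/day = 1, 2–3/day = 2.5,
4–6/day = 5, > 6/day = 7) and are replaceable via the frequency-map
argument. Daily intake of a nutrient is
`servings/day × portion × nutrient-per-100 g / 100`, summed over items;
total energy is reported in kcal/day and the per-item energies are kept
for the index.

Exclusion rules: participants lacking an FFQ at either timepoint, or with
total energy outside the pre-specified limits — women < 500 or
> 3,500 kcal/day, men < 800 or > 4,000 — are removed with one logged
reason each. Two readings of the published rule are open and were decided
as follows: the limits are strict inequalities (a woman at exactly
500 kcal/day is retained), and the energy screen applies at both
timepoints (the conservative symmetric reading; the screened timepoints
are an argument).

## 3. The dietary index and its analysis coding

The index is the energy-weighted mean of the scores of consumed items,
`DI = Σ FSᵢEᵢ / ΣEᵢ`. It is a convex combination — bounded by the
extreme item scores — and invariant to the energy unit. Zero-energy items
(water, diet drinks) are scored but cannot influence the index; this is a
known structural limitation of the energy-weighted definition, not of the
implementation. A participant with zero total energy has an undefined
index and is flagged, not dropped silently.

Tertiles are rank-based thirds: T1 holds the lowest (best-quality)
values; when n is not divisible by 3 the earlier tertiles take the extra
observation (5,921 values split 1,974/1,974/1,973). Ranks break ties by
stable participant-id order, and tied values straddling a cut share the
lower label — determinism here makes the regression tables exactly
reproducible.

The 1-year change is `year1 − baseline`, so a positive change means the
index rose, i.e. diet quality worsened. The literal reading of the
published change description would give the opposite sign, contradicting
how its results are interpreted; the orientation is therefore exposed as
an argument (`di_change(..., orientation =)`). In the change analysis,
tertiles are tertiles *of the change*, matching the change-table
convention.

## 4. Outcomes

Eight cardiovascular risk factors per timepoint: BMI (weight/height²),
waist circumference, systolic and diastolic blood pressure (mean of three
readings; a partial set of 1–2 readings uses the mean of those available —
the published methods do not state this case, and the choice maximises
usable records and is logged), fasting glucose, HDL-cholesterol,
triglycerides, and LDL-cholesterol by the Friedewald formula
`LDL = TC − HDL − TG/5` when TG < 300 mg/dL, otherwise the direct
measurement (missing, with a warning, when unavailable). Units are fixed
at mg/dL, mmHg, kg, m, cm.

Mean-value imputation applies only to the two follow-up variables imputed
in this design — BMI and diastolic BP — and preserves the observed mean;
everything else is complete-case with per-model n reported.

## 5. Regression models

`nps_lm()` fits OLS of an outcome on the index (tertile indicators with
T1 reference, or continuous) at three tiers:

| tier | covariates |
|---|---|
| crude | exposure only |
| model1 | age (y), sex, BMI (kg/m²), education (primary/secondary/university), smoking (never/current/former), total energy (kcal/day), physical activity (MET·min/week), marital status |
| full | model1 + lipid/hypertension/diabetes medication, recruitment-centre size class (and intervention arm in the prospective analysis) |

In the prospective (change-on-change) analysis, tiers above crude also
adjust for the outcome's baseline level. BMI leaves the covariate set
when BMI or waist is the outcome. Reference levels are explicit: female,
primary education, never-smoker, married, smallest centre class, control
arm. No multiple-testing correction is applied, matching the analysis
convention the package mirrors (p < 0.05).

**Cluster-robust variance.** All models use the clustered sandwich
estimator with the finite-sample factor
`(G/(G−1)) · ((N−1)/(N−k))` — the Stata `vce(cluster)` convention, which
is the software convention of the analyses this pipeline reproduces. The
implementation delegates to `sandwich::vcovCL(type = "HC1",
cadjust = TRUE)`, which equals that factor to machine precision; tests
verify it against a hand-written sandwich on small fixtures. The cluster
unit is a column name (default `cluster_id`, the recruitment centre in
the synthetic cohort) because the published analyses do not name their
cluster unit.

**Confidence intervals and p-values** default to t quantiles with G − 1
degrees of freedom (again the Stata clustered convention; with G = 23
centres the difference from 1.96 is material, t₀.₉₇₅(22) ≈ 2.07). A
normal-quantile option is provided. The trend test refits the model with
the ordinal tertile number (1/2/3) and reports the robust Wald p of that
term; it is invariant to affine recoding, and a median-of-tertile coding
can be obtained by passing a recoded column.

`run_table2()` (baseline) and `run_table3()` (1-year changes) assemble
the 8-outcome × 3-tier grids with T2/T3 coefficients, R² × 100, trend p
and the continuous coefficient; `descriptive_table()` produces
tertile-stratified baseline summaries with one-way ANOVA / chi-square
p-values, using median [P25–P75] for skewed variables on request.

## 6. The synthetic cohort generator

The generator (`sim_config()`, `generate_composition()`,
`generate_cohort()`) emulates the study conditions end to end so the
pipeline and its calibration can be tested without restricted data:

* **Composition**: 143 items across general/beverage/cheese/added-fat
  categories (mix 75/12/6/7%), nutrients drawn from per-category
  log-normal distributions spanning all scoring bands, fvln as a mixture
  with point mass at 0. Four items are constructed: one food at the score
  maximum (40), one at the minimum (−15) — so the extremes are exercised —
  and two olive oils for the sensitivity analysis.
* **Participants**: age uniform 55–75; sex 51.7% male; education,
  smoking, marital, physical activity, medication and intervention-arm
  distributions at realistic epidemiological values; 23 recruitment
  centres as the cluster unit.
* **Diets**: each participant gets a target energy (normal, men
  ~2,550 ± 250 kcal/day, women ~2,150 ± 250, truncated) and a latent
  diet-quality tilt that shifts energy shares toward lower- or
  higher-scored items (autocorrelated 0.7 across the two timepoints, so
  the index changes realistically). Item-level frequency categories are
  drawn with probabilities decaying in log-distance between the
  category's servings value and the target, after an analytic
  recalibration that corrects the coarse-grid bias in expected energy.
  Rare draws outside a safe envelope inside the exclusion limits are
  resampled, so that *natural* records never violate the energy screen —
  a precondition for testing that the exclusion stage removes exactly
  the injected violations.
* **Outcomes**: linear-Gaussian with additive centre random effects
  (SD = 0.25 × residual SD), the weakest structure under which OLS with
  cluster-robust variance is correctly specified. Baseline:
  `intercept + covariate effects + β·DI + centre effect + noise`;
  year 1 adds secular drift, an intervention-arm effect, and
  `βΔ·ΔDI`. Raw measurement fields are then decomposed so the pipeline
  has real work to do: weight from BMI and height, three BP readings
  whose mean equals the generated value exactly, total cholesterol from
  the Friedewald identity, direct LDL provided exactly when TG ≥
  300 mg/dL. Planted defaults echo published fully adjusted continuous
  coefficients in order of magnitude (e.g. 0.35 mg/dL glucose change per
  unit of index change); residual SDs sit at clinical scale.
* **Injections**: 2% of participants get implausible baseline energy
  (half all-maximum, half all-never frequencies), 2% lose their year-1
  FFQ; follow-up BMI and diastolic-BP missingness at the low rates seen
  in cohorts of this size (4/5,921 and 1/5,921). All injected sets are
  recorded in the run manifest, together with the seed and the true
  per-participant index values.

Determinism: one global seed with per-stage offsets (composition `seed`,
cohort `seed + 1`); the same configuration reproduces the dataset
byte-for-byte.

**What the generator does not emulate** — and hence what passing tests do
not show about real data: the joint covariate distribution of a real
cohort (covariates are drawn independently), FFQ measurement error and
differential misreporting, non-linear or interaction effects of diet on
risk factors, informative missingness, and seasonal/secular diet change
beyond a single autocorrelated tilt. Recovery results demonstrate that
the pipeline estimates what was planted under a correctly specified
linear model; they are not evidence about effect sizes in any real
population.

## 7. Calibration experiments and problem sizes

`recovery_experiment()` reruns the full pipeline per replicate and fits
the continuous-exposure model for all eight outcomes, summarising bias,
RMSE, empirical vs model SE, and 95% CI coverage. The packaged
acceptance test runs 500 replicates at n = 1,000 with a fixed seed and
checks |bias| < 3 Monte-Carlo SEs and coverage within [0.93, 0.97] per
outcome; unit tests use smaller sizes (a few hundred participants, ~10
replicates) to keep the default test run fast. The property suite for
the index identities uses 10,000 random baskets. The exhaustive score
audit evaluates ~2.1 million profiles and is deterministic.

## 8. Numerical and degenerate-input choices

* Threshold comparisons use exact floating-point `>`; grid audit points
  are placed at `t·(1+1e-9)+1e-9` above each threshold.
* Tertiles require ≥ 3 distinct-bearing values; an all-identical vector
  is an error (tertiles undefined), as is an all-missing imputation
  input.
* A model with fewer than 2 clusters falls back to the
  heteroskedasticity-robust estimator with a warning; rank-deficient
  designs error naming the collinear columns rather than silently
  dropping them.
* `rowsum()` over integer-coded participant × timepoint keys does the
  intake and index aggregation, keeping the pipeline fast enough for
  hundreds of Monte-Carlo replicates.

## 9. Known limitations

The score covers only the nutritional dimension (no processing,
additives, or added-sugar distinction); zero-energy items cannot move the
index; the 5-class letter mapping of the front-of-pack label is out of
scope; and the generator's realism claims are order-of-magnitude only.
The published tables this pipeline structurally mirrors were computed on
access-restricted cohort data, so their coefficient values are not
reproduction targets — the package's correctness rests on the analytic
properties and simulation calibration described above.
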