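Package: fsamnps
Title: FSAm-NPS Nutrient Profiling, Energy-Weighted Dietary Index and
    Cohort Association Models
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Implements the modified Food Standards Agency Nutrient
    Profiling System (FSAm-NPS, the algorithm underlying the Nutri-Score
    front-of-pack label): per-food scoring from per-100 g/ml composition
    with the 2015 HCSP band tables and the cheese, added-fat and beverage
    exceptions; conversion of food-frequency-questionnaire reports into
    daily gram, energy and nutrient intakes with cohort exclusion rules;
    the individual-level energy-weighted FSAm-NPS Dietary Index with
    tertile assignment and one-year change; derivation of cardiovascular
    risk-factor outcomes (Friedewald LDL, mean blood pressure, BMI, mean
    imputation); and tiered linear regression of risk factors on the index
    with cluster-robust (sandwich) variance and trend tests. A synthetic
    cohort generator with planted effects supports end-to-end testing and
    parameter-recovery experiments.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    sandwich,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    knitr,
    rmarkdown
Config/testthat/edition: 3
RoxygenNote: 7.3.3
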