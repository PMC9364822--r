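#' Assemble the analysis dataset
#'
#' Joins participant covariates and derived outcomes with the dietary
#' index at both timepoints: adds `di` (baseline), `di_y1`, `di_change`,
#' cohort tertiles of the baseline index (`di_tertile`) and of the 1-year
#' change (`di_change_tertile`), and the baseline total energy intake
#' (`energy_kcal_b`) used as a covariate.
#'
#' @param participants participant table after [derive_outcomes()].
#' @param di dietary-index table from [dietary_index()].
#' @param intakes intake table from [nutrient_intake()].
#' @return The participant table with exposure columns added; participants
#'   with an undefined index keep `NA`.
#' @export
build_analysis_data <- function(participants, di, intakes) {
  p <- participants
  # documented reference levels: female, primary, never, married, smallest
  # centre class, control arm
  canon <- list(
    sex = c("female", "male"),
    education = c("primary", "secondary", "university"),
    smoking = c("never", "current", "former"),
    marital = c("married", "widowed", "single_div_sep", "religious"),
    center_size = c("<250", "250-<300", "300-<400", ">=400"),
    intervention = c("control", "intervention")
  )
  for (nm in names(canon)) {
    if (nm %in% names(p) && !is.factor(p[[nm]])) {
      lev <- c(intersect(canon[[nm]], unique(p[[nm]])),
               setdiff(unique(p[[nm]]), canon[[nm]]))
      p[[nm]] <- factor(p[[nm]], levels = lev)
    }
  }
  get_tp <- function(tab, col, tp) {
    sel <- tab[tab$timepoint == tp, ]
    sel[[col]][match(p$participant_id, sel$participant_id)]
  }
  p$di <- get_tp(di, "di", "baseline")
  p$di_y1 <- get_tp(di, "di", "year1")
  p$di_change <- di_change(p$di, p$di_y1)
  p$di_tertile <- assign_tertiles(p$di, ids = p$participant_id)
  p$di_change_tertile <- assign_tertiles(p$di_change, ids = p$participant_id)
  p$energy_kcal_b <- get_tp(intakes, "energy_kcal", "baseline")
  p
}

#' Run the full scoring-to-analysis pipeline
#'
#' Convenience wrapper chaining every stage: score the composition table
#' (optionally with the olive-oil sensitivity reclassification), convert
#' FFQ responses to daily intakes, apply the cohort exclusion rules,
#' compute the dietary index and its tertiles/changes, derive the
#' risk-factor outcomes (with follow-up mean imputation) and return the
#' analysis dataset.
#'
#' @param composition composition table (canonical columns, see
#'   [read_composition()]).
#' @param items item table (`item_id`, `portion_size`).
#' @param responses long FFQ response table.
#' @param participants raw participant table (covariates + measurement
#'   fields, see [derive_outcomes()]).
#' @param bands band tables.
#' @param fmap frequency map.
#' @param olive_oil_ids item ids reclassified to -8 when
#'   `sensitivity_olive_oil = TRUE`.
#' @param sensitivity_olive_oil apply the olive-oil sensitivity analysis?
#' @return List with `scores`, `intakes`, `item_energy`, `di`,
#'   `exclusions` and `analysis_data` (retained participants only).
#' @export
nps_pipeline <- function(composition, items, responses, participants,
                         bands = nps_bands(), fmap = nps_frequency_map(),
                         olive_oil_ids = NULL,
                         sensitivity_olive_oil = FALSE) {
  scores <- score_foods(composition, bands)
  if (sensitivity_olive_oil) {
    if (is.null(olive_oil_ids)) stop("olive_oil_ids required for the sensitivity run")
    scores <- reclassify_olive_oil(scores, olive_oil_ids)
  }
  ni <- nutrient_intake(responses, items, composition, fmap)
  excl <- apply_exclusions(participants, ni$intakes)
  di <- dietary_index(ni$item_energy, scores)
  retained <- derive_outcomes(excl$retained)
  keep_di <- di[di$participant_id %in% retained$participant_id, ]
  keep_int <- ni$intakes[ni$intakes$participant_id %in%
                           retained$participant_id, ]
  analysis <- build_analysis_data(retained, keep_di, keep_int)
  list(scores = scores, intakes = ni$intakes, item_energy = ni$item_energy,
       di = di, exclusions = excl$exclusions, analysis_data = analysis)
}
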