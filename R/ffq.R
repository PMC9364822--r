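#' Default frequency-category map
#'
#' The nine consumption-frequency categories of the semi-quantitative FFQ,
#' mapped to servings per day with the usual Willett-style midpoints:
#' never = 0; 1-3/month = 2/30; 1/week = 1/7; 2-4/week = 3/7;
#' 5-6/week = 5.5/7; 1/day = 1; 2-3/day = 2.5; 4-6/day = 5; >6/day = 7.
#' The instrument's published endpoints pin categories 1 and 9; the
#' interior values are midpoints and can be replaced by supplying any
#' 9-row map with the same columns.
#'
#' @return Data frame with columns `frequency_category` (1-9), `label`,
#'   `servings_per_day`.
#' @export
nps_frequency_map <- function() {
  data.frame(
    frequency_category = 1:9,
    label = c("never or almost never", "1-3 per month", "1 per week",
              "2-4 per week", "5-6 per week", "1 per day", "2-3 per day",
              "4-6 per day", ">6 per day"),
    servings_per_day = c(0, 2 / 30, 1 / 7, 3 / 7, 5.5 / 7, 1, 2.5, 5, 7),
    stringsAsFactors = FALSE
  )
}

validate_fmap <- function(fmap) {
  stopifnot(is.data.frame(fmap),
            all(c("frequency_category", "servings_per_day") %in% names(fmap)))
  if (nrow(fmap) != 9L || !identical(as.integer(fmap$frequency_category), 1:9)) {
    stop("frequency map must have exactly the 9 categories 1..9")
  }
  if (any(fmap$servings_per_day < 0) || is.unsorted(fmap$servings_per_day)) {
    stop("servings_per_day must be non-negative and non-decreasing")
  }
  if (fmap$servings_per_day[1] != 0) stop("category 1 (never) must map to 0")
  fmap
}

#' Daily grams from a frequency report
#'
#' @param frequency_category integer 1-9 (vectorised).
#' @param portion_size serving size in g or ml.
#' @param fmap frequency map, see [nps_frequency_map()].
#' @return grams (or ml) per day.
#' @examples
#' daily_grams(7, 200)  # 2-3/day at 200 g -> 500 g/day
#' @export
daily_grams <- function(frequency_category, portion_size,
                        fmap = nps_frequency_map()) {
  fmap <- validate_fmap(fmap)
  fc <- as.integer(frequency_category)
  if (any(is.na(fc)) || any(fc < 1L | fc > 9L)) {
    bad <- which(is.na(fc) | fc < 1L | fc > 9L)
    stop("invalid frequency category at position(s): ",
         paste(utils::head(bad, 5), collapse = ", "))
  }
  if (any(portion_size <= 0, na.rm = TRUE)) stop("portion_size must be > 0")
  fmap$servings_per_day[fc] * portion_size
}

#' Daily nutrient and energy intake from FFQ responses
#'
#' Converts long-format FFQ responses into per-participant, per-timepoint
#' daily intakes: each reported item contributes
#' `servings/day * portion * nutrient-per-100g / 100`.  Energy is returned
#' in kcal/day (compositions carry kJ per 100 g).  The per-item energy
#' contributions needed by the dietary index are returned alongside.
#'
#' @param responses data frame `participant_id, timepoint, item_id,
#'   frequency_category`; at most one row per participant x timepoint x
#'   item; `timepoint` in `c("baseline", "year1")`.
#' @param items data frame `item_id, portion_size` (g or ml per serving).
#' @param composition composition table with canonical columns (see
#'   [read_composition()]); nutrients per 100 g/ml, energy in kJ.
#' @param fmap frequency map.
#' @return List with `intakes` (one row per participant x timepoint:
#'   `energy_kcal`, `sugars_g`, `satfat_g`, `sodium_mg`, `fiber_g`,
#'   `protein_g`, `grams`) and `item_energy` (long: `participant_id`,
#'   `timepoint`, `item_id`, `energy_kcal`).
#' @export
nutrient_intake <- function(responses, items, composition,
                            fmap = nps_frequency_map()) {
  stopifnot(is.data.frame(responses),
            all(c("participant_id", "timepoint", "item_id",
                  "frequency_category") %in% names(responses)))
  if (nrow(responses) == 0L) {
    warning("no FFQ responses supplied; returning empty intake table")
    empty <- data.frame(participant_id = character(0), timepoint = character(0),
                        energy_kcal = numeric(0), sugars_g = numeric(0),
                        satfat_g = numeric(0), sodium_mg = numeric(0),
                        fiber_g = numeric(0), protein_g = numeric(0),
                        grams = numeric(0))
    return(list(intakes = empty,
                item_energy = data.frame(participant_id = character(0),
                                         timepoint = character(0),
                                         item_id = character(0),
                                         energy_kcal = numeric(0))))
  }
  key <- paste(responses$participant_id, responses$timepoint,
               responses$item_id, sep = "\r")
  if (anyDuplicated(key)) {
    stop("duplicate response for the same participant x timepoint x item")
  }
  it <- match(responses$item_id, items$item_id)
  if (anyNA(it)) {
    stop("unresolvable item_id(s) in responses: ",
         paste(unique(responses$item_id[is.na(it)]), collapse = ", "))
  }
  co <- match(responses$item_id, composition$item_id)
  if (anyNA(co)) {
    stop("item(s) missing from composition table: ",
         paste(unique(responses$item_id[is.na(co)]), collapse = ", "))
  }
  grams <- daily_grams(responses$frequency_category,
                       items$portion_size[it], fmap)
  per100 <- grams / 100
  energy_kcal <- per100 * composition$energy[co] / 4.184
  contrib <- cbind(
    energy_kcal = energy_kcal,
    sugars_g  = per100 * composition$sugars[co],
    satfat_g  = per100 * composition$satfat[co],
    sodium_mg = per100 * composition$sodium[co],
    fiber_g   = per100 * composition$fiber[co],
    protein_g = per100 * composition$protein[co],
    grams = grams
  )
  pf <- factor(responses$participant_id)
  tf <- factor(responses$timepoint)
  grp <- (as.integer(pf) - 1L) * nlevels(tf) + as.integer(tf)
  tot <- rowsum(contrib, grp, reorder = TRUE)
  gid <- as.integer(rownames(tot))
  intakes <- data.frame(
    participant_id = levels(pf)[(gid - 1L) %/% nlevels(tf) + 1L],
    timepoint = levels(tf)[(gid - 1L) %% nlevels(tf) + 1L],
    tot, row.names = NULL, stringsAsFactors = FALSE)
  item_energy <- data.frame(
    participant_id = responses$participant_id,
    timepoint = responses$timepoint,
    item_id = responses$item_id,
    energy_kcal = energy_kcal,
    stringsAsFactors = FALSE
  )
  list(intakes = intakes, item_energy = item_energy)
}

#' Apply the cohort exclusion rules
#'
#' Excludes participants who (a) lack an FFQ at baseline or year 1, or
#' (b) have total energy intake outside the pre-specified sex-specific
#' limits at either timepoint: women below 500 or above 3,500 kcal/day,
#' men below 800 or above 4,000 kcal/day.  Limits are strict inequalities;
#' a value exactly at a limit is retained.  The operation is idempotent
#' and logs one reason per excluded participant (first violation in the
#' order missing-FFQ, low energy, high energy).
#'
#' @param cohort data frame with `participant_id` and `sex`
#'   (`"female"`/`"male"`).
#' @param intakes intake table from [nutrient_intake()] (`participant_id`,
#'   `timepoint`, `energy_kcal`), both timepoints.
#' @param limits named list of `c(low, high)` kcal/day per sex.
#' @param timepoints timepoints at which the energy screen applies
#'   (default both).
#' @return List with `retained` (subset of `cohort`) and `exclusions`
#'   (`participant_id`, `reason`).
#' @export
apply_exclusions <- function(cohort, intakes,
                             limits = list(female = c(500, 3500),
                                           male = c(800, 4000)),
                             timepoints = c("baseline", "year1")) {
  stopifnot(all(c("participant_id", "sex") %in% names(cohort)))
  bad_sex <- setdiff(unique(cohort$sex), names(limits))
  if (length(bad_sex)) stop("unknown sex code(s): ", paste(bad_sex, collapse = ", "))
  low <- vapply(limits, `[`, numeric(1), 1)[cohort$sex]
  high <- vapply(limits, `[`, numeric(1), 2)[cohort$sex]
  # energy per participant at each screened timepoint (NA = no FFQ)
  energy <- sapply(timepoints, function(tp) {
    i <- match(cohort$participant_id,
               intakes$participant_id[intakes$timepoint == tp])
    intakes$energy_kcal[intakes$timepoint == tp][i]
  })
  energy <- matrix(energy, nrow = nrow(cohort),
                   dimnames = list(NULL, timepoints))
  miss <- rowSums(is.na(energy)) > 0
  below <- !miss & rowSums(energy < low) > 0
  above <- !miss & !below & rowSums(energy > high) > 0
  reasons <- character(nrow(cohort))
  for (tp in rev(timepoints)) reasons[miss & is.na(energy[, tp])] <-
    paste0("missing_ffq_", tp)
  reasons[below] <- "energy_below_limit"
  reasons[above] <- "energy_above_limit"
  excluded <- reasons != ""
  list(
    retained = cohort[!excluded, , drop = FALSE],
    exclusions = data.frame(participant_id = cohort$participant_id[excluded],
                            reason = reasons[excluded],
                            stringsAsFactors = FALSE)
  )
}
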