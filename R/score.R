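#' Construct and validate a nutrient profile
#'
#' A nutrient profile holds the per-100 g (per-100 ml for beverages)
#' composition of one food or beverage together with its scoring category.
#'
#' @param item_id identifier.
#' @param energy energy, kJ per 100 g/ml.
#' @param sugars total sugars, g per 100 g/ml.
#' @param satfat saturated fat, g per 100 g/ml.
#' @param sodium sodium, mg per 100 g/ml.
#' @param fiber dietary fiber (AOAC), g per 100 g/ml.
#' @param protein protein, g per 100 g/ml.
#' @param fvln_pct percentage (0-100) of fruit, vegetables, legumes, nuts
#'   and rapeseed/walnut/olive oil in the product.
#' @param category scoring category: `"general"`, `"beverage"`, `"cheese"`
#'   or `"added_fat"`.
#' @param total_fat total fat, g per 100 g/ml; required for the added-fat
#'   saturated-fat-to-lipid ratio, otherwise optional.
#' @return A list of class `nutrient_profile`.
#' @export
nutrient_profile <- function(item_id, energy = 0, sugars = 0, satfat = 0,
                             sodium = 0, fiber = 0, protein = 0,
                             fvln_pct = 0, category = "general",
                             total_fat = NA_real_) {
  category <- match.arg(category, nps_categories())
  p <- list(item_id = item_id, energy = energy, sugars = sugars,
            satfat = satfat, total_fat = total_fat, sodium = sodium,
            fiber = fiber, protein = protein, fvln_pct = fvln_pct,
            category = category)
  nums <- c("energy", "sugars", "satfat", "sodium", "fiber", "protein",
            "fvln_pct")
  for (f in nums) {
    if (!is.numeric(p[[f]]) || length(p[[f]]) != 1L || is.na(p[[f]]) ||
        p[[f]] < 0) {
      stop(sprintf("profile '%s': field '%s' must be a single non-negative number",
                   item_id, f))
    }
  }
  if (p$fvln_pct > 100) stop(sprintf("profile '%s': fvln_pct must be in [0, 100]", item_id))
  if (!is.na(p$total_fat) && p$total_fat > 0 && p$satfat > p$total_fat) {
    stop(sprintf("profile '%s': satfat exceeds total_fat", item_id))
  }
  class(p) <- "nutrient_profile"
  p
}

nps_categories <- function() c("general", "beverage", "cheese", "added_fat")

# step-function lookup: points of the highest threshold strictly exceeded
band_lookup <- function(value, tab) {
  idx <- findInterval(value, tab$thresholds, left.open = TRUE)
  c(0, tab$points)[idx + 1L]
}

resolve_band <- function(component, category, bands) {
  comp <- bands$components[[component]]
  if (is.null(comp)) {
    stop(sprintf("no band table for component '%s'", component))
  }
  if (!category %in% nps_categories()) {
    stop(sprintf("unknown scoring category '%s'", category))
  }
  tab <- comp[[category]]
  if (is.null(tab)) tab <- comp[["general"]]
  if (is.null(tab)) {
    stop(sprintf("no band table for component '%s' in category '%s'",
                 component, category))
  }
  tab
}

#' Points earned by one component value
#'
#' Looks the value up in the band table for the component and scoring
#' category (falling back to the general table when the category has no
#' dedicated grid) and returns the points of the highest threshold the
#' value strictly exceeds.  For `component = "satfat"` with
#' `category = "added_fat"` the value must be the saturated-fat-to-total-fat
#' ratio in percent.
#'
#' @param value nutrient quantity per 100 g/ml (vectorised).
#' @param component one of `"energy"`, `"sugars"`, `"satfat"`, `"sodium"`,
#'   `"fiber"`, `"protein"`, `"fvln"`.
#' @param category scoring category.
#' @param bands an [nps_bands()] object.
#' @return integer points.
#' @examples
#' b <- nps_bands()
#' component_points(1500, "energy", "general", b)  # 4
#' component_points(8.1, "protein", "general", b)  # 5
#' @export
component_points <- function(value, component, category = "general",
                             bands = nps_bands()) {
  stopifnot(is.numeric(value), all(value >= 0, na.rm = TRUE))
  tab <- resolve_band(component, category, bands)
  as.integer(band_lookup(value, tab))
}

#' Score a table of foods and beverages
#'
#' Vectorised FSAm-NPS scorer.  Computes, for every row of a composition
#' table, the four A-component point values (energy, sugars, saturated
#' fat, sodium; 0-10 each), the three C-component point values (fvln,
#' fiber, protein; 0-5 each, fvln 0-10 for beverages), the protein-cap
#' decision and the total score A - C.
#'
#' Category exceptions: beverages use the beverage energy, sugar and fvln
#' grids; added fats score saturated fat on 100 * satfat/total_fat using
#' the ratio grid (total_fat = 0 scores 0 ratio points and is flagged in
#' the `warnings` attribute); cheese always keeps its protein points.
#' For all other foods protein points are discarded when the A subtotal
#' is at or above the protein cap (11) and the fvln points are below their
#' category maximum.
#'
#' @param composition data frame with columns `item_id`, `category`,
#'   `energy` (kJ), `sugars`, `satfat`, `sodium` (mg), `fiber`, `protein`,
#'   `fvln_pct` and optionally `total_fat`, all per 100 g/ml.
#' @param bands an [nps_bands()] object.
#' @return A data frame of class `food_scores` with one row per item:
#'   `item_id`, `category`, the per-component points, `a_total`,
#'   `protein_counted`, `c_total` and `total`.
#' @seealso [score_food()] for a single profile, [reclassify_olive_oil()].
#' @export
score_foods <- function(composition, bands = nps_bands()) {
  stopifnot(is.data.frame(composition))
  need <- c("item_id", "category", "energy", "sugars", "satfat", "sodium",
            "fiber", "protein", "fvln_pct")
  missing <- setdiff(need, names(composition))
  if (length(missing)) {
    stop("composition table lacks column(s): ", paste(missing, collapse = ", "))
  }
  if (anyDuplicated(composition$item_id)) stop("duplicated item_id in composition table")
  bad <- setdiff(unique(composition$category), nps_categories())
  if (length(bad)) stop("unknown scoring category: ", paste(bad, collapse = ", "))
  if (!"total_fat" %in% names(composition)) composition$total_fat <- NA_real_

  n <- nrow(composition)
  cat_ <- composition$category
  bev <- cat_ == "beverage"
  afat <- cat_ == "added_fat"

  pts_by_cat <- function(value, component) {
    out <- integer(n)
    for (cc in unique(cat_)) {
      i <- cat_ == cc
      out[i] <- component_points(value[i], component, cc, bands)
    }
    out
  }

  a_energy <- pts_by_cat(composition$energy, "energy")
  a_sugars <- pts_by_cat(composition$sugars, "sugars")
  a_sodium <- pts_by_cat(composition$sodium, "sodium")

  a_satfat <- integer(n)
  warn <- character(0)
  if (any(afat)) {
    tf <- composition$total_fat[afat]
    sf <- composition$satfat[afat]
    ratio <- ifelse(is.na(tf) | tf <= 0, 0, 100 * sf / tf)
    a_satfat[afat] <- component_points(ratio, "satfat", "added_fat", bands)
    zero_fat <- afat & (is.na(composition$total_fat) | composition$total_fat <= 0)
    if (any(zero_fat)) {
      warn <- c(warn, sprintf(
        "added-fat item '%s' has total_fat = 0; saturated-fat ratio scored 0",
        composition$item_id[zero_fat]))
    }
  }
  if (any(!afat)) {
    a_satfat[!afat] <- component_points(composition$satfat[!afat], "satfat",
                                        "general", bands)
  }
  a_total <- a_energy + a_sugars + a_satfat + a_sodium

  c_fvln <- pts_by_cat(composition$fvln_pct, "fvln")
  c_fiber <- pts_by_cat(composition$fiber, "fiber")
  c_protein_raw <- pts_by_cat(composition$protein, "protein")

  fvln_max <- ifelse(bev, max(resolve_band("fvln", "beverage", bands)$points),
                     max(resolve_band("fvln", "general", bands)$points))
  protein_counted <- a_total < bands$protein_cap | c_fvln >= fvln_max |
    cat_ == "cheese"
  c_protein <- ifelse(protein_counted, c_protein_raw, 0L)
  c_total <- c_fvln + c_fiber + as.integer(c_protein)

  out <- data.frame(
    item_id = composition$item_id, category = cat_,
    a_energy = a_energy, a_sugars = a_sugars, a_satfat = a_satfat,
    a_sodium = a_sodium, a_total = a_total,
    c_fvln = c_fvln, c_fiber = c_fiber, c_protein = as.integer(c_protein),
    protein_counted = protein_counted, c_total = c_total,
    total = a_total - c_total,
    stringsAsFactors = FALSE
  )
  class(out) <- c("food_scores", "data.frame")
  attr(out, "warnings") <- warn
  if (length(warn)) warning(paste(warn, collapse = "\n"), call. = FALSE)
  out
}

#' Score a single food or beverage
#'
#' @param profile a [nutrient_profile()] (or a list/one-row data frame with
#'   the same fields).
#' @param bands an [nps_bands()] object.
#' @return A one-row `food_scores` data frame; see [score_foods()].
#' @examples
#' oil <- nutrient_profile("virgin_olive_oil", energy = 3700, satfat = 14,
#'                         total_fat = 100, category = "added_fat")
#' score_food(oil)
#' @export
score_food <- function(profile, bands = nps_bands()) {
  df <- as.data.frame(unclass(profile)[c("item_id", "category", "energy",
                                         "sugars", "satfat", "total_fat",
                                         "sodium", "fiber", "protein",
                                         "fvln_pct")],
                      stringsAsFactors = FALSE)
  score_foods(df, bands)
}

#' A and C subtotals of one profile
#'
#' `a_subtotal()` returns the sum of the four "negative" component points;
#' `c_subtotal()` returns the "positive" subtotal after the protein-cap
#' rule, together with the protein decision.
#'
#' @inheritParams score_food
#' @param a_total A subtotal previously computed on the same profile.
#' @return `a_subtotal()`: an integer in 0..40.  `c_subtotal()`: a list
#'   with `c_total` and `protein_counted`.
#' @export
a_subtotal <- function(profile, bands = nps_bands()) {
  s <- score_food(profile, bands)
  as.integer(s$a_total)
}

#' @rdname a_subtotal
#' @export
c_subtotal <- function(profile, a_total, bands = nps_bands()) {
  s <- score_food(profile, bands)
  if (!missing(a_total) && !identical(as.integer(a_total), as.integer(s$a_total))) {
    # honour a caller-supplied A subtotal (e.g. band variants): re-apply the cap
    fvln_max <- max(resolve_band("fvln", s$category, bands)$points)
    counted <- a_total < bands$protein_cap || s$c_fvln >= fvln_max ||
      s$category == "cheese"
    raw_protein <- component_points(profile$protein, "protein", profile$category, bands)
    return(list(c_total = as.integer(s$c_fvln + s$c_fiber +
                                       if (counted) raw_protein else 0L),
                protein_counted = counted))
  }
  list(c_total = as.integer(s$c_total), protein_counted = s$protein_counted)
}

#' Exhaustive audit of the attainable score range
#'
#' Evaluates the scorer over the full grid of per-component band extremes
#' for a general-category food: for every component, the value 0 and a
#' value just above each threshold.  Returns the attained extremes of the
#' total score and of the A and C subtotals.  Under the default tables a
#' general food spans exactly -15 (healthiest) to 40 (least healthy),
#' with subtotal caps 40 (A) and 15 (C).
#'
#' @param bands an [nps_bands()] object.
#' @param category scoring category to audit (default `"general"`).
#' @return List with `max_total`, `min_total`, `max_a`, `max_c` and
#'   `n_evaluated` (number of grid profiles scored).
#' @export
score_extremes <- function(bands = nps_bands(), category = "general") {
  vals <- function(component) {
    tab <- resolve_band(component, category, bands)
    t <- tab$thresholds
    c(0, t * (1 + 1e-9) + 1e-9)   # 0 and just above each threshold
  }
  en <- vals("energy"); su <- vals("sugars"); sf <- vals("satfat")
  so <- vals("sodium"); fi <- vals("fiber"); pr <- vals("protein")
  fv <- vals("fvln")
  fv <- pmin(fv, 100)
  max_total <- -Inf; min_total <- Inf; max_a <- -Inf; max_c <- -Inf
  n_eval <- 0L
  for (e in en) {   # chunked over energy to bound memory
    g <- expand.grid(sugars = su, satfat = sf, sodium = so, fiber = fi,
                     protein = pr, fvln_pct = fv,
                     KEEP.OUT.ATTRS = FALSE)
    g$energy <- e
    g$item_id <- seq_len(nrow(g))
    g$category <- category
    g$total_fat <- pmax(g$satfat, 100)
    s <- score_foods(g, bands)
    max_total <- max(max_total, s$total)
    min_total <- min(min_total, s$total)
    max_a <- max(max_a, s$a_total)
    max_c <- max(max_c, s$c_total)
    n_eval <- n_eval + nrow(g)
  }
  list(max_total = as.integer(max_total), min_total = as.integer(min_total),
       max_a = as.integer(max_a), max_c = as.integer(max_c),
       n_evaluated = n_eval)
}

#' Olive-oil sensitivity reclassification
#'
#' Sets the total FSAm-NPS of the designated olive-oil items to -8 — the
#' healthiest value in the score, as used for fruit, vegetables or legumes
#' — leaving every other item untouched.  Used as a sensitivity analysis
#' when computing the dietary index.
#'
#' @param scores a `food_scores` data frame from [score_foods()].
#' @param olive_oil_ids identifiers of olive-oil items; must all be present
#'   in `scores`.
#' @param value replacement score (default -8).
#' @return The modified `food_scores` data frame.
#' @export
reclassify_olive_oil <- function(scores, olive_oil_ids, value = -8) {
  stopifnot(is.data.frame(scores), "item_id" %in% names(scores))
  if (length(olive_oil_ids) == 0) return(scores)
  missing <- setdiff(olive_oil_ids, scores$item_id)
  if (length(missing)) {
    stop("olive-oil id(s) not found in scores: ", paste(missing, collapse = ", "))
  }
  if (is.integer(scores$total) && isTRUE(all(value == as.integer(value)))) {
    value <- as.integer(value)
  }
  scores$total[scores$item_id %in% olive_oil_ids] <- value
  scores
}

#' Read a food composition table
#'
#' Reads a CSV with per-100 g/ml composition, harmonising units: an
#' `energy_kcal` column is converted to kJ (4.184 kJ/kcal) when
#' `energy_kj` is absent, and a `salt_g` column to sodium mg when
#' `sodium_mg` is absent.  Column names follow the documented dictionary:
#' `item_id, name, category, energy_kj (or energy_kcal), sugars_g,
#' satfat_g, fat_g, sodium_mg (or salt_g), fiber_g, protein_g, fvln_pct`.
#'
#' @param path CSV file.
#' @return A data frame with the canonical columns expected by
#'   [score_foods()] (`energy`, `sugars`, `satfat`, `total_fat`, `sodium`,
#'   `fiber`, `protein`, `fvln_pct`, `category`, plus `item_id`, `name`).
#' @export
read_composition <- function(path) {
  x <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!"energy_kj" %in% names(x)) {
    if (!"energy_kcal" %in% names(x)) stop("need energy_kj or energy_kcal column")
    x$energy_kj <- kcal_to_kj(x$energy_kcal)
  }
  if (!"sodium_mg" %in% names(x)) {
    if (!"salt_g" %in% names(x)) stop("need sodium_mg or salt_g column")
    x$sodium_mg <- salt_to_sodium_mg(x$salt_g)
  }
  need <- c("item_id", "category", "energy_kj", "sugars_g", "satfat_g",
            "sodium_mg", "fiber_g", "protein_g", "fvln_pct")
  missing <- setdiff(need, names(x))
  if (length(missing)) stop("composition CSV lacks column(s): ",
                            paste(missing, collapse = ", "))
  out <- data.frame(
    item_id = x$item_id,
    name = if ("name" %in% names(x)) x$name else x$item_id,
    category = x$category,
    energy = x$energy_kj, sugars = x$sugars_g, satfat = x$satfat_g,
    total_fat = if ("fat_g" %in% names(x)) x$fat_g else NA_real_,
    sodium = x$sodium_mg, fiber = x$fiber_g, protein = x$protein_g,
    fvln_pct = x$fvln_pct, stringsAsFactors = FALSE
  )
  out
}
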