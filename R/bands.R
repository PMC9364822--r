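#' Default FSAm-NPS band tables (2015 HCSP grids)
#'
#' Returns the point-allocation bands used by the modified FSA nutrient
#' profiling system as adopted for the Nutri-Score: per-component step
#' functions over nutrient content per 100 g (or 100 ml for beverages).
#' A value earns the points attached to the highest threshold it *strictly*
#' exceeds; values at or below the first threshold earn 0.
#'
#' "Negative" (A) components — energy (kJ), sugars (g), saturated fat (g),
#' sodium (mg) — earn 0-10 points each.  "Positive" (C) components —
#' fiber (g, AOAC), protein (g) and the fruit/vegetable/legume/nut/oil
#' percentage (fvln) — earn 0-5 points each (fvln up to 10 for beverages).
#' Beverages use dedicated energy, sugar and fvln grids; added fats score
#' the saturated-fat component on the saturated-fat-to-total-lipid ratio
#' (in percent).  The protein cap (A-subtotal at or above which protein
#' points are conditionally discarded) is 11.
#'
#' @param path optional path to a YAML file with the same structure as the
#'   bundled default (`system.file("extdata", "bands_hcsp2015.yaml",
#'   package = "fsamnps")`); when `NULL` the built-in 2015 tables are
#'   returned.
#' @return An object of class `nps_bands`: a list with elements `version`,
#'   `protein_cap` and `components` (one entry per component, each holding
#'   one or more named band tables with `thresholds` and `points`).
#' @examples
#' b <- nps_bands()
#' component_points(46, "sugars", "general", b)   # above top band -> 10
#' @export
nps_bands <- function(path = NULL) {
  if (!is.null(path)) {
    raw <- yaml::read_yaml(path)
    return(validate_bands(as_nps_bands(raw)))
  }
  band <- function(thresholds, points = seq_along(thresholds)) {
    list(thresholds = as.numeric(thresholds), points = as.numeric(points))
  }
  b <- list(
    version = "HCSP-2015",
    protein_cap = 11,
    components = list(
      energy = list(
        general  = band(c(335, 670, 1005, 1340, 1675, 2010, 2345, 2680, 3015, 3350)),
        beverage = band(c(0, 30, 60, 90, 120, 150, 180, 210, 240, 270))
      ),
      sugars = list(
        general  = band(c(4.5, 9, 13.5, 18, 22.5, 27, 31, 36, 40, 45)),
        beverage = band(c(0, 1.5, 3, 4.5, 6, 7.5, 9, 10.5, 12, 13.5))
      ),
      satfat = list(
        general   = band(1:10),
        # ratio grid: 100 * saturated fat / total fat, percent
        added_fat = band(seq(10, 64, by = 6))
      ),
      sodium  = list(general = band(seq(90, 900, by = 90))),
      fiber   = list(general = band(c(0.7, 1.4, 2.1, 2.8, 3.5))),
      protein = list(general = band(c(1.6, 3.2, 4.8, 6.4, 8))),
      fvln = list(
        general  = band(c(40, 60, 80), points = c(1, 2, 5)),
        beverage = band(c(40, 60, 80), points = c(2, 4, 10))
      )
    )
  )
  class(b) <- "nps_bands"
  validate_bands(b)
}

as_nps_bands <- function(x) {
  stopifnot(is.list(x), !is.null(x$components))
  x$protein_cap <- as.numeric(x$protein_cap)
  x$components <- lapply(x$components, function(comp) {
    lapply(comp, function(tab) {
      list(thresholds = as.numeric(tab$thresholds),
           points = as.numeric(tab$points))
    })
  })
  class(x) <- "nps_bands"
  x
}

validate_bands <- function(b) {
  if (!inherits(b, "nps_bands")) stop("not an 'nps_bands' object")
  required <- c("energy", "sugars", "satfat", "sodium", "fiber", "protein", "fvln")
  missing <- setdiff(required, names(b$components))
  if (length(missing)) {
    stop("band configuration is missing component table(s): ",
         paste(missing, collapse = ", "))
  }
  for (comp in names(b$components)) {
    for (cat in names(b$components[[comp]])) {
      tab <- b$components[[comp]][[cat]]
      if (length(tab$thresholds) != length(tab$points)) {
        stop(sprintf("bands[%s/%s]: thresholds and points differ in length",
                     comp, cat))
      }
      if (is.unsorted(tab$thresholds, strictly = TRUE)) {
        stop(sprintf("bands[%s/%s]: thresholds must be strictly increasing",
                     comp, cat))
      }
      if (is.unsorted(tab$points)) {
        stop(sprintf("bands[%s/%s]: points must be non-decreasing", comp, cat))
      }
      cap <- if (comp %in% c("fiber", "protein")) 5
             else if (comp == "fvln") { if (cat == "beverage") 10 else 5 }
             else 10
      if (max(tab$points) > cap) {
        stop(sprintf("bands[%s/%s]: maximum points %g exceed the cap %d",
                     comp, cat, max(tab$points), cap))
      }
    }
  }
  if (!is.numeric(b$protein_cap) || length(b$protein_cap) != 1L) {
    stop("protein_cap must be a single number")
  }
  b
}

#' Write band tables to a YAML file
#'
#' @param bands an `nps_bands` object.
#' @param path file to write.
#' @return `path`, invisibly.
#' @export
write_bands <- function(bands, path) {
  stopifnot(inherits(bands, "nps_bands"))
  yaml::write_yaml(unclass(bands), path)
  invisible(path)
}

#' @export
print.nps_bands <- function(x, ...) {
  cat("FSAm-NPS band tables (", x$version, ")\n", sep = "")
  cat("  protein cap: A-subtotal >= ", x$protein_cap, "\n", sep = "")
  for (comp in names(x$components)) {
    for (cat_ in names(x$components[[comp]])) {
      tab <- x$components[[comp]][[cat_]]
      cat(sprintf("  %-8s %-10s max %2d pts, thresholds: %s\n", comp, cat_,
                  as.integer(max(tab$points)),
                  paste(tab$thresholds, collapse = "/")))
    }
  }
  invisible(x)
}

#' Unit helpers for composition tables
#'
#' `salt_to_sodium_mg()` converts salt in g/100 g to sodium in mg/100 g
#' (sodium is 1/2.5 of salt by mass); `kcal_to_kj()` converts kilocalories
#' to kilojoules (factor 4.184).
#'
#' @param salt_g salt, g per 100 g.
#' @param kcal energy, kcal.
#' @return numeric vector in the target unit.
#' @export
salt_to_sodium_mg <- function(salt_g) salt_g * 1000 / 2.5

#' @rdname salt_to_sodium_mg
#' @export
kcal_to_kj <- function(kcal) kcal * 4.184
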