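#' Energy-weighted dietary index of one basket
#'
#' The individual-level FSAm-NPS Dietary Index is the energy-weighted mean
#' of the FSAm-NPS scores of all foods and beverages consumed:
#' `di = sum(FS_i * E_i) / sum(E_i)`, where `FS_i` is the item score and
#' `E_i` its mean daily energy contribution.  Items with zero energy are
#' scored but carry no weight; a basket with zero total energy has an
#' undefined index (returned as `NA`).
#'
#' @param fs item scores `FS_i`.
#' @param energy item energy contributions `E_i` (any common energy unit;
#'   the index is invariant to unit rescaling).
#' @return The dietary index (dimensionless), `NA` if `sum(energy) == 0`.
#' @examples
#' compute_di(c(0, 10), c(300, 100))  # 2.5
#' @export
compute_di <- function(fs, energy) {
  stopifnot(length(fs) == length(energy), all(energy >= 0, na.rm = TRUE))
  tot <- sum(energy)
  if (!is.finite(tot) || tot <= 0) return(NA_real_)
  sum(fs * energy) / tot
}

#' Dietary index per participant and timepoint
#'
#' Joins per-item energy contributions with food scores and evaluates the
#' energy-weighted index for every participant x timepoint.  Participants
#' whose total energy is zero are flagged (`di_defined = FALSE`, `di = NA`)
#' rather than dropped.
#'
#' @param item_energy long table `participant_id, timepoint, item_id,
#'   energy_kcal` from [nutrient_intake()].
#' @param scores `food_scores` table from [score_foods()] (use
#'   [reclassify_olive_oil()] first for the olive-oil sensitivity run).
#' @return Data frame `participant_id, timepoint, di, di_defined`.
#' @export
dietary_index <- function(item_energy, scores) {
  stopifnot(all(c("participant_id", "timepoint", "item_id", "energy_kcal")
                %in% names(item_energy)))
  i <- match(item_energy$item_id, scores$item_id)
  if (anyNA(i)) {
    stop("item(s) without a food score: ",
         paste(unique(item_energy$item_id[is.na(i)]), collapse = ", "))
  }
  fs <- scores$total[i]
  pf <- factor(item_energy$participant_id)
  tf <- factor(item_energy$timepoint)
  grp <- (as.integer(pf) - 1L) * nlevels(tf) + as.integer(tf)
  agg <- rowsum(cbind(fs * item_energy$energy_kcal,
                      item_energy$energy_kcal), grp, reorder = TRUE)
  gid <- as.integer(rownames(agg))
  di <- ifelse(agg[, 2] > 0, agg[, 1] / agg[, 2], NA_real_)
  data.frame(participant_id = levels(pf)[(gid - 1L) %/% nlevels(tf) + 1L],
             timepoint = levels(tf)[(gid - 1L) %% nlevels(tf) + 1L],
             di = di, di_defined = agg[, 2] > 0,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Rank-based tertile assignment
#'
#' Splits a cohort vector into thirds by rank: tertile 1 holds the lowest
#' values (best nutritional quality when applied to the dietary index).
#' When `n` is not divisible by 3 the earlier tertiles take the extra
#' observations (e.g. 5,921 values split 1,974/1,974/1,973).  Ranks are
#' made deterministic by breaking ties in stable `ids` order; tied values
#' straddling a cut point are then all given the lower tertile label.
#'
#' @param x numeric vector (>= 3 non-missing values).
#' @param ids optional identifiers for the stable tie order (default:
#'   input position).
#' @return Integer vector of labels 1/2/3 (`NA` where `x` is `NA`).
#' @export
assign_tertiles <- function(x, ids = seq_along(x)) {
  stopifnot(length(ids) == length(x))
  ok <- !is.na(x)
  n <- sum(ok)
  if (n < 3L) stop("need at least 3 non-missing values for tertiles")
  if (length(unique(x[ok])) == 1L) stop("all values identical; tertiles undefined")
  base <- n %/% 3L
  sizes <- base + (seq_len(3L) <= n %% 3L)
  ord <- order(x[ok], ids[ok])
  lab <- integer(n)
  lab[ord] <- rep.int(1:3, sizes)
  # ties crossing a cut share the lower label
  lab <- stats::ave(lab, x[ok], FUN = min)
  out <- rep(NA_integer_, length(x))
  out[ok] <- lab
  out
}

#' One-year change in the dietary index
#'
#' Returns the signed change so that, under the default orientation,
#' a positive value means the index increased — i.e. nutritional quality
#' decreased — over the year.  The opposite literal orientation
#' (baseline minus year 1) is available via `orientation`.
#'
#' @param baseline,year1 index values at the two timepoints.
#' @param orientation `"year1_minus_baseline"` (default) or
#'   `"baseline_minus_year1"`.
#' @return Signed change; `NA` where either value is missing.
#' @export
di_change <- function(baseline, year1,
                      orientation = c("year1_minus_baseline",
                                      "baseline_minus_year1")) {
  orientation <- match.arg(orientation)
  if (orientation == "year1_minus_baseline") year1 - baseline
  else baseline - year1
}
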