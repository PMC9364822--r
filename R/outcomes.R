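#' Body mass index
#'
#' @param weight_kg weight in kg.
#' @param height_m height in m (> 0).
#' @return BMI in kg/m^2.
#' @export
bmi <- function(weight_kg, height_m) {
  if (any(height_m <= 0, na.rm = TRUE)) stop("height must be positive")
  weight_kg / height_m^2
}

#' Mean of repeated blood-pressure readings
#'
#' Blood pressure is measured three times; the mean of the repeated
#' measures is used.  Partial reading sets (1 or 2 non-missing values)
#' use the mean of the available readings; an all-missing set yields `NA`.
#'
#' @param readings numeric vector (one measurement series) or a matrix
#'   with one row per participant and one column per reading.
#' @return Mean pressure in mmHg (vector if `readings` is a matrix).
#' @export
mean_bp <- function(readings) {
  if (is.matrix(readings) || is.data.frame(readings)) {
    m <- rowMeans(as.matrix(readings), na.rm = TRUE)
    m[is.nan(m)] <- NA_real_
    return(m)
  }
  if (all(is.na(readings))) return(NA_real_)
  mean(readings, na.rm = TRUE)
}

#' LDL cholesterol via the Friedewald formula
#'
#' `ldl = tc - hdl - tg/5` (mg/dL) whenever triglycerides are below
#' 300 mg/dL; at or above 300 the directly measured value is used instead
#' (missing, with a warning, when no direct measure is available).
#'
#' @param tc total cholesterol, mg/dL.
#' @param hdl HDL cholesterol, mg/dL.
#' @param tg triglycerides, mg/dL.
#' @param direct_ldl optional directly measured LDL, mg/dL.
#' @param tg_limit triglyceride validity limit (default 300 mg/dL).
#' @return LDL cholesterol, mg/dL.
#' @examples
#' ldl_friedewald(200, 50, 150)  # 120
#' @export
ldl_friedewald <- function(tc, hdl, tg, direct_ldl = NULL, tg_limit = 300) {
  n <- max(length(tc), length(hdl), length(tg))
  tc <- rep_len(tc, n); hdl <- rep_len(hdl, n); tg <- rep_len(tg, n)
  if (any(tc < hdl, na.rm = TRUE)) stop("total cholesterol below HDL")
  if (any(tg < 0, na.rm = TRUE)) stop("negative triglycerides")
  if (is.null(direct_ldl)) direct_ldl <- rep(NA_real_, n)
  direct_ldl <- rep_len(direct_ldl, n)
  out <- ifelse(!is.na(tg) & tg < tg_limit, tc - hdl - tg / 5, direct_ldl)
  n_lost <- sum(!is.na(tg) & tg >= tg_limit & is.na(direct_ldl))
  if (n_lost > 0) {
    warning(sprintf(
      "%d record(s) with triglycerides >= %g mg/dL and no direct LDL set to missing",
      n_lost, tg_limit))
  }
  out
}

#' Mean-value imputation
#'
#' Replaces missing entries of a cohort vector by the mean of the observed
#' entries, leaving observed values untouched, and reports which positions
#' were imputed.
#'
#' @param x numeric vector with at least one observed value.
#' @return List with `values` (completed vector) and `imputed` (integer
#'   positions that were filled in).
#' @export
impute_mean <- function(x) {
  miss <- is.na(x)
  if (all(miss)) stop("cannot impute: all values missing")
  x[miss] <- mean(x[!miss])
  list(values = x, imputed = which(miss))
}

#' One-year outcome change
#'
#' `year1 - baseline`, the same orientation as [di_change()]: a positive
#' change is an increase in the risk-factor level.
#'
#' @param baseline,year1 outcome levels at the two timepoints.
#' @return Signed change (`NA` where either value is missing).
#' @export
outcome_change <- function(baseline, year1) year1 - baseline

#' Names of the eight cardiovascular risk-factor outcomes
#'
#' @return `c("bmi", "waist", "sbp", "dbp", "glucose", "hdl", "tg", "ldl")`.
#' @export
nps_outcomes <- function() c("bmi", "waist", "sbp", "dbp", "glucose",
                             "hdl", "tg", "ldl")

#' Derive the risk-factor outcomes from raw measurement fields
#'
#' Builds the eight outcomes per timepoint from the raw cohort fields —
#' BMI from weight and height, systolic/diastolic pressure as the mean of
#' three readings, LDL by Friedewald (direct value when triglycerides are
#' at or above 300 mg/dL) — applies mean imputation to the two variables
#' imputed at follow-up (BMI and diastolic BP), and computes the one-year
#' changes.
#'
#' @param participants data frame with one row per participant holding,
#'   for each timepoint suffix `_b` (baseline) and `_y1` (year 1):
#'   `weight_kg`, `height_m`, `waist_cm`, `sbp1/2/3`, `dbp1/2/3`,
#'   `glucose`, `tc`, `hdl`, `tg` and optionally `direct_ldl`.
#' @param impute which follow-up outcome columns receive mean imputation
#'   (default `c("bmi", "dbp")`, the two imputed in this design).
#' @return The input with added columns `<outcome>_b`, `<outcome>_y1` and
#'   `<outcome>_change` for the eight outcomes, plus an attribute
#'   `imputation_log` (data frame outcome/participant_id).
#' @export
derive_outcomes <- function(participants, impute = c("bmi", "dbp")) {
  p <- participants
  for (sfx in c("b", "y1")) {
    g <- function(nm) p[[paste0(nm, "_", sfx)]]
    set <- function(nm, v) p[[paste0(nm, "_", sfx)]] <<- v
    set("bmi", bmi(g("weight_kg"), g("height_m")))
    set("waist", g("waist_cm"))
    set("sbp", mean_bp(cbind(g("sbp1"), g("sbp2"), g("sbp3"))))
    set("dbp", mean_bp(cbind(g("dbp1"), g("dbp2"), g("dbp3"))))
    set("glucose", g("glucose"))
    set("hdl", g("hdl"))
    set("tg", g("tg"))
    direct <- g("direct_ldl")
    set("ldl", ldl_friedewald(g("tc"), g("hdl"), g("tg"),
                              direct_ldl = direct))
  }
  log <- data.frame(outcome = character(0), participant_id = character(0),
                    stringsAsFactors = FALSE)
  for (nm in impute) {
    col <- paste0(nm, "_y1")
    if (anyNA(p[[col]])) {
      imp <- impute_mean(p[[col]])
      p[[col]] <- imp$values
      log <- rbind(log, data.frame(
        outcome = nm,
        participant_id = as.character(p$participant_id[imp$imputed]),
        stringsAsFactors = FALSE))
    }
  }
  for (nm in nps_outcomes()) {
    p[[paste0(nm, "_change")]] <- outcome_change(p[[paste0(nm, "_b")]],
                                                 p[[paste0(nm, "_y1")]])
  }
  attr(p, "imputation_log") <- log
  p
}
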