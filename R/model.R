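#' Cluster-robust (sandwich) covariance of a fitted model
#'
#' Clustered sandwich estimator with the finite-sample correction
#' `(G/(G-1)) * ((N-1)/(N-k))` (G clusters, N observations, k
#' coefficients), the convention used by Stata's `vce(cluster)`.  With
#' every cluster a singleton it reduces to the heteroskedasticity-robust
#' (HC) estimator up to that factor.  Fewer than 2 clusters falls back to
#' the heteroskedasticity-robust estimator with a warning.
#'
#' @param fit an `lm` fit.
#' @param cluster cluster identifiers, one per model row (no missing
#'   values).
#' @return Coefficient covariance matrix.
#' @export
cluster_vcov <- function(fit, cluster) {
  if (anyNA(cluster)) stop("missing cluster id")
  if (length(cluster) != stats::nobs(fit)) {
    stop("cluster vector length does not match the number of model rows")
  }
  G <- length(unique(cluster))
  if (G < 2L) {
    warning("fewer than 2 clusters; falling back to heteroskedasticity-robust variance")
    return(sandwich::vcovHC(fit, type = "HC1"))
  }
  sandwich::vcovCL(fit, cluster = cluster, type = "HC1", cadjust = TRUE)
}

# covariate sets of the adjustment tiers
model_covariates <- function(tier, analysis, outcome) {
  base_outcome <- sub("(_change|_b|_y1)$", "", outcome)
  covs <- switch(tier,
    crude = character(0),
    model1 = ,
    full = c("age", "sex", "bmi_b", "education", "smoking",
             "energy_kcal_b", "physical_activity", "marital")
  )
  if (tier == "full") {
    covs <- c(covs, "med_lipid", "med_htn", "med_diabetes", "center_size")
    if (analysis == "prospective") covs <- c(covs, "intervention")
  }
  if (tier %in% c("model1", "full") && analysis == "prospective") {
    covs <- c(covs, paste0(base_outcome, "_b"))
  }
  # BMI is not a covariate when adiposity itself is the outcome
  if (base_outcome %in% c("bmi", "waist")) covs <- setdiff(covs, "bmi_b")
  unique(covs)
}

#' Tiered linear model of a risk factor on the dietary index
#'
#' Fits the ordinary-least-squares regression of a cardiovascular
#' risk-factor outcome on the FSAm-NPS Dietary Index — as tertile
#' indicators (tertile 1, best quality, as reference) or as a continuous
#' term — with cluster-robust (sandwich) variance, at one of three
#' adjustment tiers:
#'
#' * `crude`: exposure only;
#' * `model1`: + age, sex, BMI, education, smoking, total energy intake,
#'   physical activity, marital status;
#' * `full`: + lipid-lowering / antihypertensive / antidiabetic medication
#'   and recruitment-centre size class (and, for the prospective change
#'   analysis, the intervention arm).
#'
#' In the prospective analysis (`analysis = "prospective"`; outcomes and
#' exposure are 1-year changes) tiers `model1` and `full` additionally
#' adjust for the outcome's baseline level.  BMI is dropped from the
#' covariates when BMI or waist circumference is the outcome.  For the
#' tertile coding, a trend p-value is computed by refitting with the
#' ordinal tertile number and taking the robust Wald p of that term.
#'
#' @param outcome outcome column name (e.g. `"glucose_b"` at baseline, or
#'   `"glucose_change"` with `analysis = "prospective"`).
#' @param data analysis data frame (see [build_analysis_data()]): one row
#'   per participant with outcome columns, `di`/`di_tertile` (and
#'   `di_change`/`di_change_tertile`), covariates and the cluster column.
#' @param exposure `"tertile"` or `"continuous"`.
#' @param tier `"crude"`, `"model1"` or `"full"`.
#' @param analysis `"cross_sectional"` or `"prospective"`.
#' @param cluster name of the cluster-id column (default `"cluster_id"`).
#' @param ci `"t"` (default; t quantile with G-1 degrees of freedom, the
#'   Stata clustered convention) or `"normal"` (1.96-style).
#' @param conf_level confidence level (default 0.95).
#' @return An object of class `nps_lm`: list with `coefficients` (table of
#'   beta, robust SE, CI, p), `exposure_rows`, `p_trend`, `n`, `n_clusters`,
#'   `r_squared` (on the tables' x100 scale), `spec` and the underlying
#'   `fit`.
#' @examples
#' sim <- simulate_cohort(sim_config(n_participants = 300, seed = 7))
#' m <- nps_lm("glucose_b", sim$analysis_data,
#'             exposure = "tertile", tier = "model1")
#' m
#' @export
nps_lm <- function(outcome, data,
                   exposure = c("tertile", "continuous"),
                   tier = c("crude", "model1", "full"),
                   analysis = c("cross_sectional", "prospective"),
                   cluster = "cluster_id",
                   ci = c("t", "normal"), conf_level = 0.95) {
  exposure <- match.arg(exposure)
  tier <- match.arg(tier)
  analysis <- match.arg(analysis)
  ci <- match.arg(ci)
  if (!outcome %in% names(data)) stop("outcome column not found: ", outcome)
  if (!cluster %in% names(data)) stop("cluster column not found: ", cluster)

  expo_var <- if (analysis == "prospective") "di_change" else "di"
  tert_var <- paste0(expo_var, "_tertile")
  covs <- model_covariates(tier, analysis, outcome)
  expo_term <- if (exposure == "tertile") {
    if (!tert_var %in% names(data)) stop("tertile column not found: ", tert_var)
    sprintf("factor(%s)", tert_var)
  } else expo_var

  vars <- c(outcome, if (exposure == "tertile") tert_var else expo_var,
            covs, cluster)
  keep <- stats::complete.cases(data[, vars, drop = FALSE])
  d <- droplevels(data[keep, , drop = FALSE])
  if (nrow(d) < length(covs) + 4L) stop("too few complete cases to fit the model")

  fml <- stats::reformulate(c(expo_term, covs), response = outcome)
  fit <- stats::lm(fml, data = d)
  if (anyNA(stats::coef(fit))) {
    stop("rank-deficient design; collinear column(s): ",
         paste(names(stats::coef(fit))[is.na(stats::coef(fit))], collapse = ", "))
  }
  cl <- d[[cluster]]
  V <- cluster_vcov(fit, cl)
  G <- length(unique(cl))
  beta <- stats::coef(fit)
  se <- sqrt(diag(V))
  mult <- if (ci == "t") stats::qt(1 - (1 - conf_level) / 2, df = max(G - 1, 1))
          else stats::qnorm(1 - (1 - conf_level) / 2)
  stat <- beta / se
  p <- if (ci == "t") 2 * stats::pt(-abs(stat), df = max(G - 1, 1))
       else 2 * stats::pnorm(-abs(stat))
  tab <- data.frame(term = names(beta), beta = unname(beta), se = unname(se),
                    ci_low = unname(beta - mult * se),
                    ci_high = unname(beta + mult * se),
                    p = unname(p), stringsAsFactors = FALSE)

  expo_rows <- if (exposure == "tertile") {
    grep(sprintf("^factor\\(%s\\)", tert_var), tab$term, value = TRUE)
  } else expo_var

  ptrend <- NA_real_
  if (exposure == "tertile") {
    d$.trend <- as.numeric(d[[tert_var]])
    fml_t <- stats::reformulate(c(".trend", covs), response = outcome)
    fit_t <- stats::lm(fml_t, data = d)
    Vt <- cluster_vcov(fit_t, cl)
    z <- stats::coef(fit_t)[".trend"] / sqrt(Vt[".trend", ".trend"])
    ptrend <- if (ci == "t") 2 * stats::pt(-abs(z), df = max(G - 1, 1))
              else 2 * stats::pnorm(-abs(z))
  }

  out <- list(coefficients = tab, exposure_rows = expo_rows,
              p_trend = unname(ptrend), n = nrow(d), n_clusters = G,
              r_squared = 100 * summary(fit)$r.squared,
              spec = list(outcome = outcome, exposure = exposure, tier = tier,
                          analysis = analysis, cluster = cluster, ci = ci,
                          conf_level = conf_level, covariates = covs,
                          formula = fml),
              fit = fit, vcov = V)
  class(out) <- "nps_lm"
  out
}

#' Trend test across dietary-index tertiles
#'
#' Replaces the tertile indicators with the ordinal tertile number in the
#' same adjusted model and returns the robust Wald p-value of that term.
#' Invariant to affine recoding of the ordinal scores.
#'
#' @inheritParams nps_lm
#' @return The trend p-value.
#' @export
p_trend <- function(outcome, data, tier = "crude",
                    analysis = c("cross_sectional", "prospective"),
                    cluster = "cluster_id", ci = c("t", "normal")) {
  m <- nps_lm(outcome, data, exposure = "tertile", tier = tier,
              analysis = analysis, cluster = cluster, ci = ci)
  m$p_trend
}

#' @export
coef.nps_lm <- function(object, ...) {
  stats::setNames(object$coefficients$beta, object$coefficients$term)
}

#' @export
vcov.nps_lm <- function(object, ...) object$vcov

#' @export
confint.nps_lm <- function(object, parm, ...) {
  tab <- object$coefficients
  ci <- cbind(tab$ci_low, tab$ci_high)
  rownames(ci) <- tab$term
  a <- (1 - object$spec$conf_level) / 2
  colnames(ci) <- paste0(format(100 * c(a, 1 - a), trim = TRUE), " %")
  if (!missing(parm)) ci <- ci[parm, , drop = FALSE]
  ci
}

#' @export
nobs.nps_lm <- function(object, ...) object$n

#' @export
residuals.nps_lm <- function(object, ...) stats::residuals(object$fit, ...)

#' @export
predict.nps_lm <- function(object, ...) stats::predict(object$fit, ...)

#' @export
print.nps_lm <- function(x, digits = 3, ...) {
  s <- x$spec
  cat(sprintf("FSAm-NPS DI %s model (%s, %s exposure)\n",
              s$analysis, s$tier, s$exposure))
  cat(sprintf("outcome: %s   n = %d, clusters = %d, R^2 x 100 = %.2f\n",
              s$outcome, x$n, x$n_clusters, x$r_squared))
  tab <- x$coefficients[x$coefficients$term %in% x$exposure_rows, ]
  for (i in seq_len(nrow(tab))) {
    cat(sprintf("  %-28s %6.*f (%.*f, %.*f)  p = %.3g\n", tab$term[i],
                digits, tab$beta[i], digits, tab$ci_low[i],
                digits, tab$ci_high[i], tab$p[i]))
  }
  if (!is.na(x$p_trend)) cat(sprintf("  P-trend = %.3g\n", x$p_trend))
  invisible(x)
}

#' @export
summary.nps_lm <- function(object, ...) {
  structure(list(object = object), class = "summary.nps_lm")
}

#' @export
print.summary.nps_lm <- function(x, ...) {
  o <- x$object
  print(o)
  cat("\nAll coefficients (robust SE):\n")
  print(o$coefficients, row.names = FALSE, digits = 4)
  cat(sprintf("\nCovariates: %s\nCI: %s, level %.2f; cluster variable '%s'\n",
              if (length(o$spec$covariates)) paste(o$spec$covariates, collapse = ", ")
              else "(none)",
              o$spec$ci, o$spec$conf_level, o$spec$cluster))
  invisible(x)
}
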