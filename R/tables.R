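outcome_labels <- function() {
  c(bmi = "BMI (kg/m^2)", waist = "Waist circumference (cm)",
    sbp = "Systolic BP (mmHg)", dbp = "Diastolic BP (mmHg)",
    glucose = "Glucose (mg/dL)", hdl = "HDL-cholesterol (mg/dL)",
    tg = "Triglycerides (mg/dL)", ldl = "LDL-cholesterol (mg/dL)")
}

run_table_grid <- function(data, analysis, outcomes, cluster, ci) {
  sfx <- if (analysis == "prospective") "_change" else "_b"
  tiers <- c("crude", "model1", "full")
  rows <- list()
  for (oc in outcomes) {
    ocol <- paste0(oc, sfx)
    for (tier in tiers) {
      mt <- nps_lm(ocol, data, exposure = "tertile", tier = tier,
                   analysis = analysis, cluster = cluster, ci = ci)
      mc <- nps_lm(ocol, data, exposure = "continuous", tier = tier,
                   analysis = analysis, cluster = cluster, ci = ci)
      tert <- mt$coefficients[mt$coefficients$term %in% mt$exposure_rows, ]
      cont <- mc$coefficients[mc$coefficients$term %in% mc$exposure_rows, ]
      rows[[length(rows) + 1L]] <- data.frame(
        outcome = oc, tier = tier, n = mt$n,
        beta_t2 = tert$beta[1], ci_low_t2 = tert$ci_low[1],
        ci_high_t2 = tert$ci_high[1],
        beta_t3 = tert$beta[2], ci_low_t3 = tert$ci_low[2],
        ci_high_t3 = tert$ci_high[2],
        r_squared = mt$r_squared, p_trend = mt$p_trend,
        beta_cont = cont$beta[1], ci_low_cont = cont$ci_low[1],
        ci_high_cont = cont$ci_high[1],
        stringsAsFactors = FALSE
      )
    }
  }
  out <- do.call(rbind, rows)
  attr(out, "analysis") <- analysis
  class(out) <- c("nps_table", "data.frame")
  out
}

#' Cross-sectional association grid (baseline)
#'
#' Fits, for each of the eight risk factors, the crude, model-1 and fully
#' adjusted regressions of the baseline outcome on the baseline dietary
#' index — tertiles (T2 and T3 versus T1) and continuous — with
#' cluster-robust variance, R^2 (x100) and the tertile trend p.
#'
#' @param data analysis data frame (see [build_analysis_data()]).
#' @param outcomes outcome set (default the eight risk factors).
#' @param cluster cluster-id column name.
#' @param ci CI convention, see [nps_lm()].
#' @return A `nps_table` data frame, one row per outcome x tier.
#' @export
run_table2 <- function(data, outcomes = nps_outcomes(),
                       cluster = "cluster_id", ci = "t") {
  run_table_grid(data, "cross_sectional", outcomes, cluster, ci)
}

#' Prospective association grid (1-year changes)
#'
#' Same grid as [run_table2()] over 1-year outcome changes regressed on
#' tertiles of the 1-year dietary-index change (and the continuous
#' change), with baseline-outcome adjustment in tiers above crude and
#' intervention-arm adjustment in the full tier.
#'
#' @inheritParams run_table2
#' @export
run_table3 <- function(data, outcomes = nps_outcomes(),
                       cluster = "cluster_id", ci = "t") {
  run_table_grid(data, "prospective", outcomes, cluster, ci)
}

#' @export
print.nps_table <- function(x, digits = 2, ...) {
  analysis <- attr(x, "analysis")
  cat(sprintf("FSAm-NPS DI %s associations (T1 = reference)\n",
              if (identical(analysis, "prospective")) "1-year change"
              else "baseline"))
  fmt <- function(b, lo, hi) sprintf("%.*f (%.*f, %.*f)", digits, b,
                                     digits, lo, digits, hi)
  labs <- outcome_labels()
  for (oc in unique(x$outcome)) {
    cat(sprintf("%s  (n = %d)\n", labs[[oc]], x$n[x$outcome == oc][1]))
    sub <- x[x$outcome == oc, ]
    for (i in seq_len(nrow(sub))) {
      cat(sprintf("  %-8s T2 %s | T3 %s | R2 %5.2f | P-trend %.3g | cont. %s\n",
                  sub$tier[i],
                  fmt(sub$beta_t2[i], sub$ci_low_t2[i], sub$ci_high_t2[i]),
                  fmt(sub$beta_t3[i], sub$ci_low_t3[i], sub$ci_high_t3[i]),
                  sub$r_squared[i], sub$p_trend[i],
                  fmt(sub$beta_cont[i], sub$ci_low_cont[i], sub$ci_high_cont[i])))
    }
  }
  invisible(x)
}

#' Forest plot of continuous-exposure coefficients
#'
#' Base-graphics forest plot of the continuous dietary-index coefficient
#' (with its CI) per outcome for one adjustment tier.
#'
#' @param x an `nps_table`.
#' @param tier which tier to plot (default `"full"`).
#' @param ... passed to [graphics::plot()].
#' @export
plot.nps_table <- function(x, tier = "full", ...) {
  sub <- x[x$tier == tier, ]
  k <- nrow(sub)
  ylim <- c(0.5, k + 0.5)
  xlim <- range(0, sub$ci_low_cont, sub$ci_high_cont)
  graphics::plot(NA, xlim = xlim, ylim = ylim, yaxt = "n",
                 xlab = "beta per dietary-index unit (95% CI)", ylab = "",
                 main = sprintf("Continuous FSAm-NPS DI, %s tier", tier), ...)
  graphics::abline(v = 0, lty = 2, col = "grey50")
  ys <- rev(seq_len(k))
  graphics::segments(sub$ci_low_cont, ys, sub$ci_high_cont, ys)
  graphics::points(sub$beta_cont, ys, pch = 16)
  graphics::axis(2, at = ys, labels = outcome_labels()[sub$outcome],
                 las = 1, cex.axis = 0.75)
  invisible(x)
}

#' Baseline characteristics by dietary-index tertile
#'
#' Table-1-style summary: for continuous variables the mean and SD (or
#' median and interquartile range for variables listed in `skewed`) per
#' tertile with a one-way ANOVA p-value; for categorical variables the
#' percentage (count) per level and tertile with a chi-square p-value.
#'
#' @param data analysis data frame with a `di_tertile` column.
#' @param variables named character vector mapping column names to
#'   `"continuous"` or `"categorical"`.
#' @param skewed continuous columns summarised as median [P25-P75].
#' @param tertile_var tertile column (default `"di_tertile"`).
#' @return Data frame with one row per variable (or variable level):
#'   `variable`, `level`, `t1`, `t2`, `t3`, `overall`, `p`.
#' @export
descriptive_table <- function(data, variables, skewed = character(0),
                              tertile_var = "di_tertile") {
  stopifnot(tertile_var %in% names(data))
  tert <- data[[tertile_var]]
  if (any(table(factor(tert, levels = 1:3)) == 0)) {
    stop("empty tertile; cannot summarise")
  }
  rows <- list()
  for (v in names(variables)) {
    type <- match.arg(variables[[v]], c("continuous", "categorical"))
    x <- data[[v]]
    if (type == "continuous") {
      summarise <- function(z) {
        z <- z[!is.na(z)]
        if (v %in% skewed) {
          q <- stats::quantile(z, c(0.25, 0.5, 0.75), names = FALSE)
          sprintf("%.3g [%.3g-%.3g]", q[2], q[1], q[3])
        } else sprintf("%.3g ± %.3g", mean(z), stats::sd(z))
      }
      p <- summary(stats::aov(x ~ factor(tert)))[[1]][["Pr(>F)"]][1]
      rows[[length(rows) + 1L]] <- data.frame(
        variable = v, level = NA_character_,
        t1 = summarise(x[tert == 1]), t2 = summarise(x[tert == 2]),
        t3 = summarise(x[tert == 3]), overall = summarise(x),
        p = p, stringsAsFactors = FALSE)
    } else {
      tab <- table(x, tert)
      p <- stats::chisq.test(tab)$p.value
      for (lv in rownames(tab)) {
        cell <- function(tt) {
          n <- tab[lv, as.character(tt)]
          sprintf("%.1f%% (%d)", 100 * n / sum(tab[, as.character(tt)]), n)
        }
        ntot <- sum(tab[lv, ])
        rows[[length(rows) + 1L]] <- data.frame(
          variable = v, level = lv,
          t1 = cell(1), t2 = cell(2), t3 = cell(3),
          overall = sprintf("%.1f%% (%d)", 100 * ntot / sum(tab), ntot),
          p = if (lv == rownames(tab)[1]) p else NA_real_,
          stringsAsFactors = FALSE)
      }
    }
  }
  do.call(rbind, rows)
}
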