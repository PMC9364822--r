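#' Configuration for the synthetic cohort generator
#'
#' Defines the study conditions the generator emulates: a 143-item
#' semi-quantitative FFQ with nine frequency categories, participants aged
#' 55-75 with overweight/obesity and metabolic-syndrome-range biomarkers
#' recruited in a small number of centres (the cluster unit), and outcomes
#' generated from a linear-Gaussian model with additive cluster random
#' effects and known ("planted") effects of the dietary index — the
#' weakest structure under which OLS with cluster-robust variance is
#' correctly specified.
#'
#' Planted effect defaults echo the order of magnitude of fully adjusted
#' continuous coefficients reported for this design (e.g. a 0.35 mg/dL
#' glucose change per unit of 1-year index change).
#'
#' @param n_participants cohort size (default 1000, the size used by the
#'   packaged recovery experiments).
#' @param n_items number of FFQ items (default 143).
#' @param n_clusters number of recruitment centres (default 23).
#' @param seed integer seed; per-stage substreams are derived from it
#'   (composition: `seed`; cohort: `seed + 1`).
#' @param beta_baseline named numeric: planted effect of the baseline
#'   dietary index on each baseline outcome (per index unit).
#' @param beta_change named numeric: planted effect of the 1-year index
#'   change on each outcome change.
#' @param sigma_baseline,sigma_change named numeric residual SDs.
#' @param cluster_sd_frac cluster random-effect SD as a fraction of the
#'   residual SD (applied to both timepoints' linear predictors).
#' @param miss_bmi,miss_dbp follow-up missingness rates for weight (hence
#'   BMI) and the diastolic readings (defaults echo 4 and 1 of 5,921).
#' @param implausible_rate fraction of participants injected with
#'   out-of-range total energy at baseline (half extreme-high, half zero).
#' @param missing_ffq_rate fraction of participants whose year-1 FFQ is
#'   removed.
#' @param category_mix item category proportions.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_participants = 1000, n_items = 143,
                       n_clusters = 23, seed = 1,
                       beta_baseline = c(bmi = 0.08, waist = 0.22,
                                         sbp = 0.10, dbp = -0.11,
                                         glucose = 0.11, hdl = -0.21,
                                         tg = 0.36, ldl = 0.35),
                       beta_change = c(bmi = 0.11, waist = 0.28,
                                       sbp = 0.17, dbp = 0.15,
                                       glucose = 0.35, hdl = -0.02,
                                       tg = 1.75, ldl = -0.34),
                       sigma_baseline = c(bmi = 3.2, waist = 8.5,
                                          sbp = 16, dbp = 9.5,
                                          glucose = 28, hdl = 10,
                                          tg = 52, ldl = 31),
                       sigma_change = c(bmi = 1.0, waist = 3.0,
                                        sbp = 10, dbp = 7,
                                        glucose = 14, hdl = 5,
                                        tg = 40, ldl = 20),
                       cluster_sd_frac = 0.25,
                       miss_bmi = 4 / 5921, miss_dbp = 1 / 5921,
                       implausible_rate = 0.02,
                       missing_ffq_rate = 0.02,
                       category_mix = c(general = 0.75, beverage = 0.12,
                                        cheese = 0.06, added_fat = 0.07)) {
  oc <- nps_outcomes()
  for (nm in c("beta_baseline", "beta_change", "sigma_baseline",
               "sigma_change")) {
    v <- get(nm)
    extra <- setdiff(names(v), oc)
    if (length(extra)) stop(nm, ": unknown outcome(s): ",
                            paste(extra, collapse = ", "))
    missing <- setdiff(oc, names(v))
    if (length(missing)) stop(nm, ": missing outcome(s): ",
                              paste(missing, collapse = ", "))
    if (grepl("^sigma", nm) && any(v < 0)) stop(nm, " must be non-negative")
  }
  stopifnot(n_items >= 10, n_clusters >= 2, cluster_sd_frac >= 0,
            implausible_rate >= 0, implausible_rate <= 1,
            missing_ffq_rate >= 0, missing_ffq_rate <= 1,
            miss_bmi >= 0, miss_bmi <= 1, miss_dbp >= 0, miss_dbp <= 1)
  cfg <- list(n_participants = n_participants, n_items = n_items,
              n_clusters = n_clusters, seed = as.integer(seed),
              beta_baseline = beta_baseline[oc], beta_change = beta_change[oc],
              sigma_baseline = sigma_baseline[oc],
              sigma_change = sigma_change[oc],
              cluster_sd_frac = cluster_sd_frac,
              miss_bmi = miss_bmi, miss_dbp = miss_dbp,
              implausible_rate = implausible_rate,
              missing_ffq_rate = missing_ffq_rate,
              category_mix = category_mix)
  class(cfg) <- "sim_config"
  cfg
}

rlnorm_at <- function(n, median, sdlog) stats::rlnorm(n, log(median), sdlog)

#' Generate a synthetic food composition table
#'
#' Draws per-100 g/ml nutrient values from documented per-category
#' log-normal distributions spanning all scoring bands, with an fvln
#' mixture placing point mass at 0.  Four items are constructed rather
#' than drawn: one general food attaining the score maximum (every A
#' component above its top band, no C points), one attaining the minimum
#' (no A points, every C component above its top band), and two olive-oil
#' added fats (flagged in `is_olive_oil`, used by the sensitivity
#' analysis).  Deterministic under the configuration seed.
#'
#' @param config a [sim_config()].
#' @return Composition data frame with the canonical scoring columns plus
#'   `portion_size` (g or ml per serving) and `is_olive_oil`.
#' @export
generate_composition <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  n <- config$n_items
  ids <- sprintf("item_%03d", seq_len(n))
  cats <- sample(names(config$category_mix), n, replace = TRUE,
                 prob = config$category_mix)
  # reserve the first four slots for constructed items
  cats[1:2] <- "general"
  cats[3:4] <- "added_fat"

  draw <- function(cat, k) {
    switch(cat,
      general = data.frame(
        energy = rlnorm_at(k, 800, 0.9), sugars = rlnorm_at(k, 5, 1.1),
        satfat = rlnorm_at(k, 2, 1.0), sodium = rlnorm_at(k, 300, 1.0),
        fiber = rlnorm_at(k, 2, 0.8), protein = rlnorm_at(k, 6, 0.9),
        fvln_pct = ifelse(stats::runif(k) < 0.5, 0,
                          100 * stats::rbeta(k, 2, 2)),
        total_fat = NA_real_,
        portion_size = stats::runif(k, 30, 250)),
      beverage = data.frame(
        energy = rlnorm_at(k, 120, 0.8), sugars = rlnorm_at(k, 6, 0.8),
        satfat = rlnorm_at(k, 0.1, 0.5), sodium = rlnorm_at(k, 20, 0.8),
        fiber = rlnorm_at(k, 0.2, 0.6), protein = rlnorm_at(k, 1.5, 1.0),
        fvln_pct = ifelse(stats::runif(k) < 0.6, 0,
                          100 * stats::rbeta(k, 2, 1)),
        total_fat = NA_real_,
        portion_size = stats::runif(k, 100, 330)),
      cheese = data.frame(
        energy = rlnorm_at(k, 1400, 0.3), sugars = rlnorm_at(k, 2, 0.5),
        satfat = rlnorm_at(k, 15, 0.4), sodium = rlnorm_at(k, 600, 0.4),
        fiber = rep(0, k), protein = rlnorm_at(k, 22, 0.2),
        fvln_pct = rep(0, k), total_fat = NA_real_,
        portion_size = stats::runif(k, 30, 60)),
      added_fat = {
        tf <- stats::runif(k, 80, 100)
        ratio <- stats::runif(k, 8, 70)
        data.frame(
          energy = rlnorm_at(k, 3000, 0.2), sugars = rlnorm_at(k, 0.2, 0.5),
          satfat = ratio * tf / 100, sodium = rlnorm_at(k, 10, 1.0),
          fiber = rep(0, k), protein = rlnorm_at(k, 0.3, 0.5),
          fvln_pct = rep(0, k), total_fat = tf,
          portion_size = stats::runif(k, 10, 15))
      })
  }
  parts <- vector("list", n)
  for (cc in unique(cats)) {
    idx <- which(cats == cc)
    d <- draw(cc, length(idx))
    for (j in seq_along(idx)) parts[[idx[j]]] <- d[j, ]
  }
  comp <- do.call(rbind, parts)
  comp <- cbind(data.frame(item_id = ids, category = cats,
                           stringsAsFactors = FALSE), comp)
  comp$total_fat <- ifelse(is.na(comp$total_fat), comp$satfat * 2,
                           comp$total_fat)
  comp$is_olive_oil <- FALSE

  # constructed extremes and olive oils
  comp[1, c("energy", "sugars", "satfat", "sodium", "fiber", "protein",
            "fvln_pct", "total_fat")] <-
    list(3400, 46, 11, 950, 0, 0, 0, 25)
  comp[2, c("energy", "sugars", "satfat", "sodium", "fiber", "protein",
            "fvln_pct", "total_fat")] <-
    list(0, 0, 0, 0, 4, 9, 100, 0.5)
  for (i in 3:4) {
    comp[i, c("energy", "sugars", "satfat", "sodium", "fiber", "protein",
              "fvln_pct", "total_fat")] <-
      list(3700, 0, 14, 0.5, 0, 0.1, 100, 100)
    comp$is_olive_oil[i] <- TRUE
  }
  comp$portion_size[3:4] <- 12
  rownames(comp) <- NULL
  comp
}

# map a target servings/day to a stochastic frequency category:
# probabilities decay with log-scale distance between the category's
# servings value and the target
category_weights <- function(mu, servings, tau = 0.3, delta = 0.02) {
  logd <- outer(log(mu + delta), log(servings + delta), "-")
  exp(-logd^2 / (2 * tau^2))
}

# expected servings/day of the stochastic category draw at target mu
expected_servings <- function(mu, servings, tau = 0.3, delta = 0.02) {
  w <- category_weights(mu, servings, tau, delta)
  as.vector(w %*% servings) / rowSums(w)
}

sample_categories <- function(mu, servings, tau = 0.3, delta = 0.02) {
  n <- length(mu)
  w <- category_weights(mu, servings, tau, delta)
  for (j in 2:ncol(w)) w[, j] <- w[, j] + w[, j - 1]   # row-wise cumsum
  u <- stats::runif(n) * w[, ncol(w)]
  as.integer(rowSums(u > w) + 1L)
}

#' Generate a synthetic PREDIMED-Plus-like cohort
#'
#' Produces two-timepoint FFQ responses, participant covariates within the
#' eligibility ranges (age 55-75, BMI centred in the overweight/obese
#' range, metabolic-syndrome-range biomarkers), recruitment-centre
#' clusters, and raw outcome measurement fields generated from the planted
#' linear model: baseline outcome = intercept + covariate effects +
#' beta_baseline x DI + cluster effect + noise; year-1 outcome = baseline
#' value + secular drift + intervention effect + beta_change x (DI change)
#' + cluster effect + noise.  The dietary index entering the linear
#' predictor is computed from the generated responses with the package's
#' own scoring pipeline before any record injection.
#'
#' Injected violations (recorded in the manifest): a fraction of
#' participants get a baseline energy intake outside the pre-specified
#' limits (all-maximum or all-never frequencies) and a disjoint fraction
#' lose their year-1 FFQ entirely.
#'
#' @param config a [sim_config()].
#' @param composition composition table from [generate_composition()].
#' @return List with `responses` (long FFQ table), `participants` (raw
#'   covariate/measurement table), `items` (item/portion table) and
#'   `manifest` (seed, injected id sets, true planted effects, realised
#'   dietary-index summaries).
#' @export
generate_cohort <- function(config, composition) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed + 1L)
  n <- config$n_participants
  n_it <- nrow(composition)
  pid <- sprintf("p%05d", seq_len(n))
  oc <- nps_outcomes()

  ## covariates -------------------------------------------------------
  cluster_id <- sprintf("centre_%02d", sample.int(config$n_clusters, n,
                                                  replace = TRUE))
  centre_sizes <- sample(c("<250", "250-<300", "300-<400", ">=400"),
                         config$n_clusters, replace = TRUE)
  names(centre_sizes) <- sprintf("centre_%02d", seq_len(config$n_clusters))
  sex <- sample(c("male", "female"), n, replace = TRUE,
                prob = c(0.517, 0.483))
  part <- data.frame(
    participant_id = pid, cluster_id = cluster_id, sex = sex,
    age = stats::runif(n, 55, 75),
    education = sample(c("primary", "secondary", "university"), n, TRUE,
                       prob = c(0.50, 0.29, 0.21)),
    smoking = sample(c("never", "current", "former"), n, TRUE,
                     prob = c(0.45, 0.12, 0.43)),
    marital = sample(c("married", "widowed", "single_div_sep", "religious"),
                     n, TRUE, prob = c(0.77, 0.10, 0.12, 0.01)),
    physical_activity = stats::rgamma(n, shape = 1.17, scale = 2140),
    med_lipid = stats::rbinom(n, 1, 0.50),
    med_htn = stats::rbinom(n, 1, 0.60),
    med_diabetes = stats::rbinom(n, 1, 0.25),
    intervention = sample(c("control", "intervention"), n, TRUE),
    center_size = unname(centre_sizes[cluster_id]),
    stringsAsFactors = FALSE
  )

  ## FFQ responses ----------------------------------------------------
  serv <- nps_frequency_map()$servings_per_day
  e_item <- composition$portion_size * composition$energy / 100 / 4.184
  scores <- score_foods(composition)
  z <- as.numeric(scale(scores$total))
  w_base <- stats::rgamma(n_it, shape = 0.8, scale = 1)   # item popularity

  target <- ifelse(sex == "male",
                   pmin(pmax(stats::rnorm(n, 2550, 250), 1800), 3000),
                   pmin(pmax(stats::rnorm(n, 2150, 250), 1500), 2600))
  q_b <- stats::rnorm(n, 0, 0.6)
  q_y <- 0.7 * q_b + sqrt(1 - 0.7^2) * stats::rnorm(n, 0, 0.6)
  target_y <- target + stats::rnorm(n, 0, 100)

  draw_freqs <- function(q, tgt) {
    W <- outer(q, z, function(qq, zz) exp(qq * zz)) *
      rep(w_base, each = n)                       # n x n_it weights
    shares <- W / rowSums(W)
    # servings/day targets; (near-)zero-energy items (e.g. water) cannot
    # carry an energy share, so they get a fixed moderate target
    e_safe <- pmax(e_item, 5)
    mu <- pmin(shares * tgt / rep(e_safe, each = n), 7)
    # one calibration pass: the coarse ordinal grid biases the realised
    # servings away from mu, so rescale targets by the analytic ratio of
    # intended to expected total energy
    eserv <- matrix(expected_servings(as.vector(mu), serv), nrow = n)
    implied <- as.vector((eserv * rep(e_item, each = n)) %*% rep(1, n_it))
    mu <- pmin(mu * (tgt / implied), 7)
    freq <- matrix(sample_categories(as.vector(mu), serv), nrow = n)
    # natural diets must sit strictly inside the exclusion limits:
    # resample rare out-of-envelope draws (coarse-grid tail events)
    lo <- ifelse(sex == "male", 900, 600)
    hi <- ifelse(sex == "male", 3900, 3400)
    for (attempt in 1:25) {
      realised <- as.vector(matrix(serv[freq], nrow = n) %*% e_item)
      bad <- which(realised < lo | realised > hi)
      if (!length(bad)) break
      freq[bad, ] <- matrix(sample_categories(as.vector(mu[bad, , drop = FALSE]),
                                              serv), nrow = length(bad))
    }
    freq
  }
  freq_b <- draw_freqs(q_b, target)
  freq_y <- draw_freqs(q_y, target_y)

  ## planted outcomes use the natural (pre-injection) dietary index ----
  energy_b <- matrix(serv[freq_b], nrow = n) * rep(e_item, each = n)
  energy_y <- matrix(serv[freq_y], nrow = n) * rep(e_item, each = n)
  di_b <- as.vector(energy_b %*% scores$total) / rowSums(energy_b)
  di_y <- as.vector(energy_y %*% scores$total) / rowSums(energy_y)
  di_delta <- di_y - di_b

  ## outcome generation ------------------------------------------------
  cl_int <- match(part$cluster_id, names(centre_sizes))
  alpha <- c(bmi = 32.4, waist = NA, sbp = 139, dbp = 80.7, glucose = 113,
             hdl = 47, tg = 150, ldl = 117)
  drift <- c(bmi = -0.5, waist = -1.2, sbp = -1, dbp = -0.5, glucose = -1,
             hdl = 0.5, tg = -4, ldl = -2)
  arm_eff <- c(bmi = -0.6, waist = -1.5, sbp = -1.5, dbp = -0.8,
               glucose = -2, hdl = 0.8, tg = -6, ldl = -2)
  arm <- as.numeric(part$intervention == "intervention")
  di_c <- di_b - 8       # centre near a typical index value
  age_c <- part$age - 65
  y_b <- y_y <- list()
  for (k in oc) {
    a_k <- if (k == "waist") ifelse(sex == "male", 111, 104) else alpha[[k]]
    covar_eff <- switch(k,
      sbp = 0.35 * age_c, dbp = 0.12 * age_c,
      glucose = -2e-4 * (part$physical_activity - 2500),
      hdl = ifelse(sex == "male", -4, 0),
      tg = ifelse(sex == "male", 8, 0),
      0)
    if (!k %in% c("bmi", "waist") && length(y_b)) {
      covar_eff <- covar_eff + switch(k, sbp = 0.4, dbp = 0.25,
                                      glucose = 0.8, 0) *
        (y_b[["bmi"]] - 32.4)
    }
    cl_b <- stats::rnorm(config$n_clusters, 0,
                         config$cluster_sd_frac * config$sigma_baseline[[k]])
    cl_y <- stats::rnorm(config$n_clusters, 0,
                         config$cluster_sd_frac * config$sigma_change[[k]])
    y_b[[k]] <- a_k + covar_eff + config$beta_baseline[[k]] * di_c +
      cl_b[cl_int] + stats::rnorm(n, 0, config$sigma_baseline[[k]])
    y_y[[k]] <- y_b[[k]] + drift[[k]] + arm_eff[[k]] * arm +
      config$beta_change[[k]] * di_delta +
      cl_y[cl_int] + stats::rnorm(n, 0, config$sigma_change[[k]])
  }
  # physiological floors keep derived quantities well-defined
  for (k in c("glucose", "hdl", "tg")) {
    y_b[[k]] <- pmax(y_b[[k]], 20)
    y_y[[k]] <- pmax(y_y[[k]], 20)
  }
  y_b[["ldl"]] <- pmax(y_b[["ldl"]], 30)
  y_y[["ldl"]] <- pmax(y_y[["ldl"]], 30)

  ## decompose into raw measurement fields ----------------------------
  height <- stats::rnorm(n, ifelse(sex == "male", 1.68, 1.58), 0.06)
  add_fields <- function(p, y, sfx) {
    p[[paste0("height_m_", sfx)]] <- height
    p[[paste0("weight_kg_", sfx)]] <- y$bmi * height^2
    p[[paste0("waist_cm_", sfx)]] <- y$waist
    for (bp in c("sbp", "dbp")) {
      d1 <- stats::rnorm(n, 0, 3); d2 <- stats::rnorm(n, 0, 3)
      p[[paste0(bp, "1_", sfx)]] <- y[[bp]] + d1
      p[[paste0(bp, "2_", sfx)]] <- y[[bp]] + d2
      p[[paste0(bp, "3_", sfx)]] <- y[[bp]] - d1 - d2
    }
    p[[paste0("glucose_", sfx)]] <- y$glucose
    p[[paste0("hdl_", sfx)]] <- y$hdl
    p[[paste0("tg_", sfx)]] <- y$tg
    p[[paste0("tc_", sfx)]] <- y$ldl + y$hdl + y$tg / 5
    p[[paste0("direct_ldl_", sfx)]] <- ifelse(y$tg >= 300, y$ldl, NA_real_)
    p
  }
  part <- add_fields(part, y_b, "b")
  part <- add_fields(part, y_y, "y1")

  ## injected violations and missingness ------------------------------
  n_imp <- round(config$implausible_rate * n)
  n_mff <- round(config$missing_ffq_rate * n)
  pool <- sample(pid, n_imp + n_mff)
  imp_ids <- pool[seq_len(n_imp)]
  mff_ids <- setdiff(pool, imp_ids)
  imp_high <- imp_ids[seq_len(ceiling(n_imp / 2))]
  imp_low <- setdiff(imp_ids, imp_high)
  freq_b[pid %in% imp_high, ] <- 9L
  freq_b[pid %in% imp_low, ] <- 1L

  miss_w <- stats::runif(n) < config$miss_bmi
  miss_d <- stats::runif(n) < config$miss_dbp
  part$weight_kg_y1[miss_w] <- NA_real_
  part$dbp1_y1[miss_d] <- NA_real_
  part$dbp2_y1[miss_d] <- NA_real_
  part$dbp3_y1[miss_d] <- NA_real_

  responses <- rbind(
    data.frame(participant_id = rep(pid, times = n_it),
               timepoint = "baseline",
               item_id = rep(composition$item_id, each = n),
               frequency_category = as.vector(freq_b),
               stringsAsFactors = FALSE),
    data.frame(participant_id = rep(pid[!pid %in% mff_ids], times = n_it),
               timepoint = "year1",
               item_id = rep(composition$item_id, each = sum(!pid %in% mff_ids)),
               frequency_category = as.vector(freq_y[!pid %in% mff_ids, ]),
               stringsAsFactors = FALSE)
  )

  manifest <- list(
    seed = config$seed,
    injected_implausible = sort(imp_ids),
    injected_missing_ffq = sort(mff_ids),
    missing_bmi_y1 = pid[miss_w], missing_dbp_y1 = pid[miss_d],
    beta_baseline = config$beta_baseline, beta_change = config$beta_change,
    di_baseline_mean = mean(di_b), di_baseline_sd = stats::sd(di_b),
    di_change_sd = stats::sd(di_delta),
    true_di_baseline = stats::setNames(di_b, pid),
    true_di_change = stats::setNames(di_delta, pid)
  )
  list(responses = responses, participants = part,
       items = composition[, c("item_id", "portion_size")],
       manifest = manifest)
}

#' Generate a cohort and run the full pipeline on it
#'
#' @param config a [sim_config()].
#' @param sensitivity_olive_oil apply the olive-oil reclassification when
#'   computing the index.
#' @return The [nps_pipeline()] result, plus `composition`, `cohort` (the
#'   raw generator output) and `manifest`.
#' @export
simulate_cohort <- function(config = sim_config(),
                            sensitivity_olive_oil = FALSE) {
  comp <- generate_composition(config)
  coh <- generate_cohort(config, comp)
  res <- nps_pipeline(comp, coh$items, coh$responses, coh$participants,
                      olive_oil_ids = comp$item_id[comp$is_olive_oil],
                      sensitivity_olive_oil = sensitivity_olive_oil)
  res$composition <- comp
  res$cohort <- coh
  res$manifest <- coh$manifest
  res
}

#' Monte-Carlo parameter-recovery experiment
#'
#' Repeatedly generates a cohort, runs the complete pipeline (scoring,
#' intake, exclusions, dietary index, outcome derivation, regression) and
#' fits the continuous-exposure model for every outcome, then summarises
#' bias, RMSE, empirical SE and confidence-interval coverage of the
#' planted effects.
#'
#' @param config a [sim_config()]; replicate r uses seed `config$seed + r`.
#' @param n_reps number of replicates (>= 2).
#' @param analysis `"prospective"` (recover `beta_change`; default) or
#'   `"cross_sectional"` (recover `beta_baseline`).
#' @param tier adjustment tier used for recovery (default `"full"`, the
#'   correctly specified model).
#' @param ci CI convention passed to [nps_lm()].
#' @return Data frame with one row per outcome: `beta_true`, `mean_est`,
#'   `bias`, `mcse` (Monte-Carlo SE of the mean estimate), `rmse`,
#'   `empirical_se`, `mean_model_se`, `coverage`, `n_reps`.
#' @export
recovery_experiment <- function(config = sim_config(), n_reps = 100,
                                analysis = c("prospective",
                                             "cross_sectional"),
                                tier = "full", ci = "t") {
  stopifnot(n_reps >= 2)
  analysis <- match.arg(analysis)
  oc <- nps_outcomes()
  truth <- if (analysis == "prospective") config$beta_change
           else config$beta_baseline
  sfx <- if (analysis == "prospective") "_change" else "_b"
  est <- se <- cover <- matrix(NA_real_, n_reps, length(oc),
                               dimnames = list(NULL, oc))
  for (r in seq_len(n_reps)) {
    cfg <- config
    cfg$seed <- config$seed + r
    sim <- simulate_cohort(cfg)
    dat <- sim$analysis_data
    for (k in oc) {
      m <- nps_lm(paste0(k, sfx), dat, exposure = "continuous",
                  tier = tier, analysis = analysis, ci = ci)
      row <- m$coefficients[m$coefficients$term == m$exposure_rows, ]
      est[r, k] <- row$beta
      se[r, k] <- row$se
      cover[r, k] <- row$ci_low <= truth[[k]] && truth[[k]] <= row$ci_high
    }
  }
  data.frame(
    outcome = oc,
    beta_true = unname(truth[oc]),
    mean_est = colMeans(est),
    bias = colMeans(est) - unname(truth[oc]),
    mcse = apply(est, 2, stats::sd) / sqrt(n_reps),
    rmse = sqrt(colMeans((est - rep(unname(truth[oc]), each = n_reps))^2)),
    empirical_se = apply(est, 2, stats::sd),
    mean_model_se = colMeans(se),
    coverage = colMeans(cover),
    n_reps = n_reps,
    row.names = NULL, stringsAsFactors = FALSE
  )
}
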