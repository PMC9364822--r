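# small deterministic analysis frame with planted linear structure
toy_analysis_data <- function(n = 120, seed = 17, beta = 2, noise = 0.5,
                              n_clusters = 6) {
  set.seed(seed)
  d <- data.frame(
    participant_id = sprintf("p%03d", 1:n),
    cluster_id = sample(sprintf("c%d", 1:n_clusters), n, TRUE),
    di = runif(n, 2, 15),
    age = runif(n, 55, 75),
    sex = factor(sample(c("female", "male"), n, TRUE),
                 c("female", "male")),
    education = factor(sample(c("primary", "secondary", "university"),
                              n, TRUE),
                       c("primary", "secondary", "university")),
    smoking = factor(sample(c("never", "current", "former"), n, TRUE),
                     c("never", "current", "former")),
    marital = factor(sample(c("married", "widowed"), n, TRUE),
                     c("married", "widowed")),
    physical_activity = runif(n, 200, 6000),
    energy_kcal_b = runif(n, 1500, 3200),
    bmi_b = runif(n, 27, 40),
    med_lipid = rbinom(n, 1, 0.5), med_htn = rbinom(n, 1, 0.5),
    med_diabetes = rbinom(n, 1, 0.2),
    center_size = factor(sample(c("<250", ">=400"), n, TRUE),
                         c("<250", ">=400")),
    intervention = factor(sample(c("control", "intervention"), n, TRUE),
                          c("control", "intervention")),
    stringsAsFactors = FALSE
  )
  d$di_tertile <- assign_tertiles(d$di, d$participant_id)
  d$glucose_b <- 100 + beta * d$di + rnorm(n, 0, noise)
  d$di_change <- rnorm(n, 0, 2)
  d$di_change_tertile <- assign_tertiles(d$di_change, d$participant_id)
  d$glucose_change <- 1 + 0.4 * d$di_change + rnorm(n, 0, noise)
  d
}

test_that("noiseless crude fit interpolates exactly", {
  d <- toy_analysis_data(n = 10, noise = 0, beta = 2)
  # a zero-residual fit is the point here; lm warns about perfection
  m <- suppressWarnings(
    nps_lm("glucose_b", d, exposure = "continuous", tier = "crude"))
  expect_equal(unname(coef(m)["di"]), 2, tolerance = 1e-10)
})

test_that("cluster-robust vcov equals the brute-force sandwich", {
  set.seed(2)
  d <- data.frame(x = rnorm(10), y = rnorm(10),
                  g = rep(c("a", "b", "c"), c(4, 3, 3)))
  f <- lm(y ~ x, d)
  V <- cluster_vcov(f, d$g)
  Vb <- bruteforce_cluster_vcov(f, d$g)
  expect_lt(max(abs(V - Vb) / abs(Vb)), 1e-10)
})

test_that("singleton clusters reduce to the HC estimator up to the factor", {
  set.seed(4)
  n <- 25
  d <- data.frame(x = rnorm(n), y = rnorm(n), g = seq_len(n))
  f <- lm(y ~ x, d)
  V <- cluster_vcov(f, d$g)
  # HC0 meat with the documented correction (G = n here)
  X <- model.matrix(f); e <- resid(f); k <- ncol(X)
  hc0 <- solve(crossprod(X)) %*% crossprod(X * e) %*% solve(crossprod(X))
  expect_equal(V, (n / (n - 1)) * ((n - 1) / (n - k)) * hc0,
               tolerance = 1e-12, ignore_attr = TRUE)
})

test_that("within-cluster correlation inflates robust SEs over naive OLS", {
  set.seed(6)
  G <- 20; m <- 25
  g <- rep(1:G, each = m)
  x <- rnorm(G)[g] + rnorm(G * m, sd = 0.2)   # cluster-correlated regressor
  y <- 1 + x + rnorm(G)[g] * 2 + rnorm(G * m)
  f <- lm(y ~ x)
  se_naive <- summary(f)$coefficients["x", "Std. Error"]
  se_cl <- sqrt(cluster_vcov(f, g)["x", "x"])
  expect_gt(se_cl, 1.5 * se_naive)
})

test_that("point estimates ignore clustering; duplication leaves them fixed", {
  d <- toy_analysis_data()
  m1 <- nps_lm("glucose_b", d, exposure = "continuous", tier = "model1")
  f_plain <- lm(m1$spec$formula, data = d)
  expect_equal(unname(coef(m1)), unname(coef(f_plain)), tolerance = 1e-12)
  dd <- rbind(d, d)
  m2 <- nps_lm("glucose_b", dd, exposure = "continuous", tier = "model1")
  expect_equal(coef(m2), coef(m1), tolerance = 1e-10)
})

test_that("cluster_vcov input validation and degenerate fallbacks", {
  set.seed(12)
  d <- data.frame(x = rnorm(12), y = rnorm(12))
  f <- lm(y ~ x, d)
  expect_error(cluster_vcov(f, c(rep(1, 11), NA)), "missing cluster")
  expect_error(cluster_vcov(f, 1:5), "length")
  expect_warning(V <- cluster_vcov(f, rep(1, 12)), "fewer than 2 clusters")
  expect_true(all(is.finite(V)))
})

test_that("adjustment tiers assemble the documented covariate sets", {
  d <- toy_analysis_data()
  m0 <- nps_lm("glucose_b", d, tier = "crude")
  expect_length(m0$spec$covariates, 0)
  m1 <- nps_lm("glucose_b", d, tier = "model1")
  expect_setequal(m1$spec$covariates,
                  c("age", "sex", "bmi_b", "education", "smoking",
                    "energy_kcal_b", "physical_activity", "marital"))
  mf <- nps_lm("glucose_b", d, tier = "full")
  expect_setequal(setdiff(mf$spec$covariates, m1$spec$covariates),
                  c("med_lipid", "med_htn", "med_diabetes", "center_size"))
  expect_false("intervention" %in% mf$spec$covariates)  # cross-sectional
  # prospective: baseline outcome enters, and the full tier adds the arm
  d$glucose_change <- d$glucose_change
  mp <- nps_lm("glucose_change", d, tier = "model1",
               analysis = "prospective")
  expect_true("glucose_b" %in% mp$spec$covariates)
  mpf <- nps_lm("glucose_change", d, tier = "full",
                analysis = "prospective")
  expect_true(all(c("glucose_b", "intervention") %in% mpf$spec$covariates))
  # BMI leaves the covariates when adiposity is the outcome
  d$bmi_change <- rnorm(nrow(d)); d$waist_b <- runif(nrow(d), 90, 120)
  mb <- nps_lm("bmi_change", d, tier = "model1", analysis = "prospective")
  expect_false("bmi_b" %in% mb$spec$covariates)
  mw <- nps_lm("waist_b", d, tier = "model1")
  expect_false("bmi_b" %in% mw$spec$covariates)
})

test_that("trend p is invariant to affine recoding of the ordinal term", {
  d <- toy_analysis_data(seed = 23)
  m <- nps_lm("glucose_b", d, exposure = "tertile", tier = "crude")
  d2 <- d
  d2$di_tertile <- d$di_tertile - 1          # {0,1,2} coding
  m2 <- nps_lm("glucose_b", d2, exposure = "tertile", tier = "crude")
  expect_equal(m$p_trend, m2$p_trend, tolerance = 1e-12)
  # strongly monotone outcome -> small trend p even at t(5) df
  expect_lt(m$p_trend, 1e-3)
})

test_that("rank-deficient designs fail loudly", {
  d <- toy_analysis_data()
  d$energy_kcal_b <- d$age * 2   # exact collinearity
  expect_error(nps_lm("glucose_b", d, tier = "model1"), "collinear")
})

test_that("nps_lm accessors behave like a fitted model object", {
  d <- toy_analysis_data()
  m <- nps_lm("glucose_b", d, exposure = "continuous", tier = "model1")
  expect_s3_class(m, "nps_lm")
  expect_identical(nobs(m), nrow(d))
  expect_length(residuals(m), nrow(d))
  ci <- confint(m, "di")
  expect_lt(ci[1], coef(m)["di"]); expect_gt(ci[2], coef(m)["di"])
  expect_identical(nrow(vcov(m)), nrow(confint(m)))
  expect_identical(ncol(vcov(m)), nrow(confint(m)))
  expect_output(print(m), "cross_sectional")
  expect_output(print(summary(m)), "robust SE")
  # t vs normal CI conventions differ as the quantiles dictate
  mn <- nps_lm("glucose_b", d, exposure = "continuous", tier = "model1",
               ci = "normal")
  expect_lt(mn$coefficients$ci_high[2] - mn$coefficients$ci_low[2],
            m$coefficients$ci_high[2] - m$coefficients$ci_low[2])
})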