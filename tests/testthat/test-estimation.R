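# Estimation: least-squares and clustered-covariance oracles, family
# fixed effects vs dummy-variable least squares, stratified slope
# differences, and the logistic robustness fit.

# build a design_sample directly from a data frame
raw_sample <- function(d, design = "between", outcome = "cito_z") {
  gxefam:::new_design_sample(design, outcome, d, NULL, 1L)
}

simple_formula <- function(vars, outcome = "cito_z", design = "between") {
  terms <- lapply(vars, function(v)
    if (length(strsplit(v, ":")[[1]]) > 1)
      gxefam:::term_row(strsplit(v, ":")[[1]], "interaction")
    else gxefam:::term_row(v, "main"))
  if (design == "within")
    terms <- c(terms, list(gxefam:::term_row("family_fe",
                                             "fixed-effect-absorbed")))
  gxefam:::new_model_formula(design, outcome, NULL, terms)
}

test_that("an exact line is recovered exactly", {
  d <- data.frame(person_id = as.character(1:3), family_id = as.character(1:3),
                  x = c(0, 1, 2), cito_z = c(1, 2, 3))
  fit <- fit_linear_clustered(raw_sample(d), simple_formula("x"))
  expect_equal(unname(fit$coef), c(1, 1), tolerance = 1e-12)
  expect_identical(fit$estimator, "ols")
})

test_that("coefficients and clustered covariance match independent oracles", {
  co <- ols_fixture(n = 120, seed = 7)
  s <- sample_from(co)
  f <- expand_interacted("between", "cito_z", "cog")
  fit <- fit_linear_clustered(s, f)
  # normal-equations oracle
  pr <- gxefam:::prepare_xy(s, f)
  X <- pr$X[, names(fit$coef)]
  beta_or <- solve(crossprod(X), crossprod(X, pr$y))
  expect_equal(unname(fit$coef), unname(drop(beta_or)), tolerance = 1e-10)
  # clustered covariance oracle: sandwich::vcovCL with the CR1 factor
  dd <- as.data.frame(X[, -1])
  names(dd) <- paste0("v", seq_len(ncol(dd)))
  dd$y <- pr$y
  lmfit <- lm(y ~ ., dd)
  V_or <- sandwich::vcovCL(lmfit, cluster = pr$cluster, type = "HC1")
  expect_equal(unname(fit$vcov), unname(V_or), tolerance = 1e-9)
  # degrees of freedom follow the cluster count
  expect_identical(fit$df, length(unique(pr$cluster)) - 1L)
  expect_true(all(fit$p >= 0 & fit$p <= 1))
  # covariance is symmetric positive semi-definite
  expect_equal(fit$vcov, t(fit$vcov), tolerance = 1e-12)
  expect_true(all(eigen(fit$vcov, symmetric = TRUE,
                        only.values = TRUE)$values > -1e-10))
})

test_that("singleton clusters reduce to the heteroskedasticity-robust covariance", {
  co <- ols_fixture(n = 60, seed = 13)
  d <- sample_from(co)$data
  d$family_id <- d$person_id           # every observation its own cluster
  fit <- fit_linear_clustered(raw_sample(d),
                              simple_formula(c("pgi_cog", "ses")))
  X <- cbind(1, d$pgi_cog, d$ses)
  e <- d$cito_z - X %*% solve(crossprod(X), crossprod(X, d$cito_z))
  bread <- solve(crossprod(X))
  hc0 <- bread %*% crossprod(X * as.vector(e)) %*% bread
  N <- nrow(X); K <- ncol(X)
  expect_equal(unname(fit$vcov),
               unname(hc0 * N / (N - 1) * (N - 1) / (N - K)),
               tolerance = 1e-10)
})

test_that("collinear columns are dropped with a log, not an error", {
  co <- ols_fixture(n = 60, seed = 19)
  d <- sample_from(co)$data
  d$dup <- d$pgi_cog
  fit <- fit_linear_clustered(raw_sample(d),
                              simple_formula(c("pgi_cog", "dup")))
  expect_identical(fit$dropped, "dup")
  expect_true("pgi_cog" %in% names(fit$coef))
})

test_that("family fixed effects equal dummy-variable least squares", {
  set.seed(33)
  nfam <- 30
  d <- data.frame(
    person_id = as.character(1:(2 * nfam)),
    family_id = rep(sprintf("F%02d", 1:nfam), each = 2),
    pgi_cog = rnorm(2 * nfam), pgi_noncog = rnorm(2 * nfam),
    pc1 = rnorm(2 * nfam))
  d$math7 <- 0.4 * d$pgi_cog - 0.2 * d$pgi_noncog + 0.1 * d$pc1 +
    rep(rnorm(nfam), each = 2) + rnorm(2 * nfam, 0, 0.5)
  s <- raw_sample(d, "within", "math7")
  f <- simple_formula(c("pgi_cog", "pgi_noncog", "pc1"), "math7", "within")
  fit <- fit_fe_clustered(s, f)
  lsdv <- lm(math7 ~ pgi_cog + pgi_noncog + pc1 + factor(family_id), d)
  expect_equal(unname(fit$coef),
               unname(coef(lsdv)[c("pgi_cog", "pgi_noncog", "pc1")]),
               tolerance = 1e-8)
  # clustered LSDV covariance oracle for the slope block
  V_or <- sandwich::vcovCL(lsdv, cluster = d$family_id, type = "HC1")
  expect_equal(unname(fit$vcov),
               unname(V_or[c("pgi_cog", "pgi_noncog", "pc1"),
                           c("pgi_cog", "pgi_noncog", "pc1")]),
               tolerance = 1e-8)
})

test_that("family-constant terms are inestimable; SES is a contract error", {
  set.seed(35)
  nfam <- 20
  d <- data.frame(
    person_id = as.character(1:(2 * nfam)),
    family_id = rep(sprintf("F%02d", 1:nfam), each = 2),
    pgi_cog = rnorm(2 * nfam),
    ses = rep(rbinom(nfam, 1, 0.5), each = 2),
    platform = rep(sample(c("A", "B"), nfam, TRUE), each = 2))
  d$math7 <- 0.3 * d$pgi_cog + rnorm(2 * nfam)
  s <- raw_sample(d, "within", "math7")
  fit <- fit_fe_clustered(s, simple_formula(c("pgi_cog", "platform"),
                                            "math7", "within"))
  expect_identical(fit$inestimable, "platformB")
  expect_false("platformB" %in% names(fit$coef))
  expect_error(
    fit_fe_clustered(s, simple_formula(c("pgi_cog", "ses"),
                                       "math7", "within")),
    class = "gxefam_contract_error")
  # an MZ-pair-only sample has no within-family index variation
  d2 <- d
  d2$pgi_cog <- rep(rnorm(nfam), each = 2)
  expect_error(
    fit_fe_clustered(raw_sample(d2, "within", "math7"),
                     simple_formula("pgi_cog", "math7", "within")),
    class = "gxefam_singular_error")
})

test_that("stratified slope difference equals the fully interacted pooled FE", {
  set.seed(37)
  nfam <- 60
  d <- data.frame(
    person_id = as.character(1:(2 * nfam)),
    family_id = rep(sprintf("F%02d", 1:nfam), each = 2),
    pgi_cog = rnorm(2 * nfam), pgi_noncog = rnorm(2 * nfam),
    ses = rep(rbinom(nfam, 1, 0.5), each = 2))
  d$math7 <- 0.4 * d$pgi_cog - 0.15 * d$pgi_cog * d$ses +
    rep(rnorm(nfam), each = 2) + rnorm(2 * nfam, 0, 0.6)
  s <- raw_sample(d, "within", "math7")
  f <- simple_formula(c("pgi_cog", "pgi_noncog"), "math7", "within")
  hi <- fit_stratified_fe(s, f, 1)
  lo <- fit_stratified_fe(s, f, 0)
  dd <- diff_stratified(hi, lo)
  # pooled FE with every regressor interacted with SES: since SES is
  # family-constant and partitions families, the interaction coefficient
  # equals the stratified difference
  fp <- simple_formula(c("pgi_cog", "pgi_noncog", "pgi_cog:ses",
                         "pgi_noncog:ses"), "math7", "within")
  pooled <- fit_fe_clustered(s, fp)
  expect_equal(dd$diff[dd$term == "pgi_cog"],
               unname(pooled$coef["pgi_cog:ses"]), tolerance = 1e-8)
  expect_equal(dd$diff[dd$term == "pgi_noncog"],
               unname(pooled$coef["pgi_noncog:ses"]), tolerance = 1e-8)
  # se combines the independent strata
  expect_equal(dd$se, sqrt(hi$se[dd$term]^2 + lo$se[dd$term]^2),
               ignore_attr = TRUE)
  # identical strata give a difference of exactly zero
  d0 <- d; d0$ses <- rep(c(0, 1), nfam)   # not family-constant: rebuild
  dsame <- rbind(transform(d, ses = 0),
                 transform(d, ses = 1,
                           family_id = paste0(family_id, "b"),
                           person_id = paste0(person_id, "b")))
  ssame <- raw_sample(dsame, "within", "math7")
  dd0 <- diff_stratified(fit_stratified_fe(ssame, f, 1),
                         fit_stratified_fe(ssame, f, 0))
  expect_equal(dd0$diff, c(0, 0), tolerance = 1e-12)
  # an empty stratum errors
  dall <- transform(d, ses = 1)
  expect_error(fit_stratified_fe(raw_sample(dall, "within", "math7"), f, 0),
               class = "gxefam_stratum_error")
})

test_that("stratified difference recovers a simulated interaction", {
  cfg <- cohort_config(
    n_families = 1500, n_loci = 150, seed = 43,
    effects = default_effects(math10 = list(gamma_cog = -0.1)))
  co <- simulate_cohort(cfg)
  s <- build_within(co, "math10", seed = 3)
  f <- expand_baseline("within", "math10")
  dd <- diff_stratified(fit_stratified_fe(s, f, 1),
                        fit_stratified_fe(s, f, 0), terms = "pgi_cog")
  expect_lt(abs(dd$diff - (-0.1)), 2 * dd$se)
})

test_that("logistic fit matches closed forms and agrees with the LPM in sign", {
  # null: balanced outcome independent of the regressor
  set.seed(47)
  n <- 400
  d <- data.frame(person_id = as.character(1:n),
                  family_id = as.character(1:n),
                  pgi_cog = rnorm(n), track = rbinom(n, 1, 0.5))
  fit0 <- fit_logit_clustered(raw_sample(d, outcome = "track"),
                              simple_formula("pgi_cog", "track"))
  expect_lt(abs(fit0$coef["pgi_cog"]), 3 * fit0$se["pgi_cog"])
  # 2x2 contingency closed form: odds ratio 16, log-odds ln(16)
  d2 <- data.frame(person_id = as.character(1:100),
                   family_id = as.character(1:100),
                   g = rep(c(0, 1), each = 50),
                   track = c(rep(1, 40), rep(0, 10), rep(1, 10), rep(0, 40)))
  fit2 <- fit_logit_clustered(raw_sample(d2, outcome = "track"),
                              simple_formula("g", "track"))
  expect_equal(unname(fit2$coef["g"]), -log(16), tolerance = 1e-6)
  # clustered covariance oracle via sandwich on the same glm
  gl <- glm(track ~ g, binomial, d2)
  V_or <- sandwich::vcovCL(gl, cluster = d2$family_id)
  expect_equal(unname(fit2$vcov), unname(V_or), tolerance = 1e-6)
  # strong-interaction fixture: logit and LPM agree on the interaction sign
  co <- ols_fixture(n = 300, seed = 53)
  s <- sample_from(co, outcome = "track")
  f <- simple_formula(c("pgi_cog", "ses", "pgi_cog:ses"), "track")
  flpm <- fit_linear_clustered(s, f)
  flog <- fit_logit_clustered(s, f)
  expect_identical(flpm$estimator, "lpm")
  expect_identical(sign(unname(flpm$coef["pgi_cog:ses"])),
                   sign(unname(flog$coef["pgi_cog:ses"])))
  # perfect separation is a divergence error
  dsep <- data.frame(person_id = as.character(1:40),
                     family_id = as.character(1:40),
                     x = c(rnorm(20, -3), rnorm(20, 3)),
                     track = rep(c(0, 1), each = 20))
  expect_error(fit_logit_clustered(raw_sample(dsep, outcome = "track"),
                                   simple_formula("x", "track")),
               class = "gxefam_divergence_error")
})
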