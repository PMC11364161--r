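# Estimation: least squares / linear probability models, family
# fixed-effects, SES-stratified fixed-effects slope differences, and
# logistic regression, all with family-clustered sandwich covariance.
#
# Covariance convention: CR1 small-sample factor
# G/(G-1) * (N-1)/(N-K), with t tests on G-1 degrees of freedom (G =
# number of family clusters), the de-facto convention of the applied
# family-regression literature. For the fixed-effects estimator K counts
# the absorbed family intercepts.

# drop collinear columns by pivoted QR; returns kept X and dropped names
drop_collinear <- function(X, tol = 1e-9) {
  if (ncol(X) == 0) return(list(X = X, dropped = character(0)))
  qrx <- qr(X, tol = tol)
  keep <- sort(qrx$pivot[seq_len(qrx$rank)])
  list(X = X[, keep, drop = FALSE],
       dropped = colnames(X)[setdiff(seq_len(ncol(X)), keep)])
}

# CR1 family-clustered sandwich covariance for a least-squares fit
cr1_vcov <- function(X, resid, cluster, k_absorbed = 0L) {
  N <- nrow(X); K <- ncol(X) + k_absorbed
  G <- length(unique(cluster))
  bread <- chol2inv(chol(crossprod(X)))
  S <- rowsum(X * resid, cluster)
  meat <- crossprod(S)
  adj <- G / (G - 1) * (N - 1) / (N - K)
  V <- adj * bread %*% meat %*% bread
  dimnames(V) <- list(colnames(X), colnames(X))
  V
}

new_fit_result <- function(coef, vcov, df, n_obs, n_clusters, estimator,
                           formula, dropped = character(0),
                           inestimable = character(0), term_map = list(),
                           x_means = NULL, r_squared = NA_real_) {
  se <- sqrt(diag(vcov))
  if (any(!is.finite(se)) || any(se <= 0))
    singular_error("non-positive clustered standard error; fit is degenerate")
  t <- coef / se
  p <- 2 * stats::pt(-abs(t), df)
  structure(list(coef = coef, vcov = vcov, se = se, t = t, p = p, df = df,
                 n_obs = n_obs, n_clusters = n_clusters,
                 estimator = estimator, formula = formula,
                 dropped = dropped, inestimable = inestimable,
                 term_map = term_map, x_means = x_means,
                 r_squared = r_squared),
            class = "fit_result")
}

#' @export
print.fit_result <- function(x, ...) {
  cat(sprintf("<fit_result> %s: n = %d, clusters = %d, df = %d\n",
              x$estimator, x$n_obs, x$n_clusters, x$df))
  tab <- data.frame(estimate = x$coef, se = x$se, t = x$t, p = x$p)
  print(utils::head(tab, 12))
  if (nrow(tab) > 12) cat(sprintf("  ... %d more terms\n", nrow(tab) - 12))
  if (length(x$dropped))
    cat("dropped (collinear):", paste(x$dropped, collapse = ", "), "\n")
  if (length(x$inestimable))
    cat("inestimable (family-constant):",
        paste(x$inestimable, collapse = ", "), "\n")
  invisible(x)
}

#' Tidy a fit into a long coefficient table
#'
#' @param fit a `fit_result`.
#' @return data frame with one row per estimated term.
#' @export
tidy_fit <- function(fit) {
  data.frame(design = fit$formula$design %||% NA_character_,
             outcome = fit$formula$outcome %||% NA_character_,
             focal_pgi = fit$formula$focal_pgi %||% NA_character_,
             term = names(fit$coef), estimate = unname(fit$coef),
             se = unname(fit$se), t = unname(fit$t), p = unname(fit$p),
             n = fit$n_obs, n_clusters = fit$n_clusters,
             estimator = fit$estimator, stringsAsFactors = FALSE)
}

prepare_xy <- function(sample, formula, intercept = TRUE) {
  d <- sample$data
  ycol <- outcome_column(formula$outcome)
  y <- as.numeric(d[[ycol]])
  built <- build_design_matrix(formula, d)
  X <- built$X
  if (intercept)
    X <- cbind(`(Intercept)` = rep(1, nrow(d)), X)
  list(X = X, y = y, cluster = d$family_id, term_map = built$term_map)
}

#' Least-squares fit with family-clustered standard errors
#'
#' Ordinary least squares (a linear probability model when the outcome is
#' binary) with CR1 family-clustered sandwich covariance and t tests on
#' G - 1 degrees of freedom. Collinear columns are dropped and logged on
#' the result. Linear-probability predictions are not truncated to `[0, 1]`.
#'
#' @param sample a `design_sample`.
#' @param formula a `model_formula`.
#' @return a `fit_result`.
#' @export
fit_linear_clustered <- function(sample, formula) {
  pr <- prepare_xy(sample, formula)
  dc <- drop_collinear(pr$X)
  X <- dc$X
  if (ncol(X) == 0) singular_error("no estimable columns remain")
  G <- length(unique(pr$cluster))
  if (G < 2) singular_error("clustered covariance needs at least 2 families")
  qrx <- qr(X)
  beta <- qr.coef(qrx, pr$y)
  e <- pr$y - drop(X %*% beta)
  V <- cr1_vcov(X, e, pr$cluster)
  est <- if (is_binary01(pr$y)) "lpm" else "ols"
  r2 <- 1 - sum(e^2) / sum((pr$y - mean(pr$y))^2)
  new_fit_result(beta, V, df = G - 1L, n_obs = nrow(X), n_clusters = G,
                 estimator = est, formula = formula, dropped = dc$dropped,
                 term_map = pr$term_map, x_means = colMeans(X),
                 r_squared = r2)
}

#' Family fixed-effects fit with clustered standard errors
#'
#' Demeans outcome and regressors within family and applies clustered least
#' squares to the transformed data (numerically identical to including one
#' indicator per family). Regressors that are constant within every family
#' cannot be estimated by design: family SES in the formula is a contract
#' error, a family-constant control (e.g. the platform indicator) is
#' reported as inestimable and dropped, and a polygenic-index term with zero
#' within-family variance (e.g. a sample of monozygotic pairs) is a
#' singularity error. The CR1 factor counts the absorbed family intercepts.
#'
#' @inheritParams fit_linear_clustered
#' @return a `fit_result` with an `inestimable` field.
#' @export
fit_fe_clustered <- function(sample, formula) {
  if (formula$design != "within")
    contract_error("family fixed-effects fits are defined for the within design")
  has_ses_main <- any(vapply(formula$terms, function(tr)
    identical(tr$vars, "ses"), TRUE))
  if (has_ses_main)
    contract_error("SES is family-constant: its main term cannot be estimated under family fixed effects")
  pr <- prepare_xy(sample, formula, intercept = FALSE)
  fam <- pr$cluster
  G <- length(unique(fam))
  if (G < 2) singular_error("need at least 2 families")
  demean <- function(M) M - rowsum(M, fam)[fam, , drop = FALSE] /
    as.vector(table(fam)[fam])
  Xd <- demean(pr$X)
  yd <- drop(demean(matrix(pr$y)))
  wconst <- apply(abs(Xd), 2, max) < 1e-10
  if (any(wconst)) {
    bad <- colnames(pr$X)[wconst]
    pgi_bad <- grepl("^pgi", bad)
    if (any(pgi_bad))
      singular_error(paste("zero within-family variance in:",
                           paste(bad[pgi_bad], collapse = ", ")))
  }
  inest <- colnames(pr$X)[wconst]
  Xd <- Xd[, !wconst, drop = FALSE]
  dc <- drop_collinear(Xd)
  Xd <- dc$X
  if (ncol(Xd) == 0) singular_error("no within-family-varying regressors remain")
  beta <- qr.coef(qr(Xd), yd)
  e <- yd - drop(Xd %*% beta)
  V <- cr1_vcov(Xd, e, fam, k_absorbed = G)
  new_fit_result(beta, V, df = G - 1L, n_obs = nrow(Xd), n_clusters = G,
                 estimator = "fe", formula = formula,
                 dropped = dc$dropped, inestimable = inest,
                 term_map = pr$term_map, x_means = colMeans(pr$X))
}

#' SES-stratified family fixed-effects fit
#'
#' Fits the within-family model separately for families in one SES stratum.
#' Family SES partitions whole families, so stratification is equivalent to
#' a pooled fixed-effects model in which every regressor is interacted with
#' SES.
#'
#' @inheritParams fit_linear_clustered
#' @param ses_stratum 0 (low) or 1 (high).
#' @return a `fit_result`.
#' @export
fit_stratified_fe <- function(sample, formula, ses_stratum) {
  stopifnot(ses_stratum %in% c(0, 1))
  d <- sample$data[sample$data$ses == ses_stratum, , drop = FALSE]
  if (length(unique(d$family_id)) < 2)
    gxe_stop("gxefam_stratum_error",
             sprintf("SES stratum %d has fewer than 2 families", ses_stratum))
  sub <- new_design_sample(sample$design, sample$outcome, d,
                          sample$selection_log, sample$seed)
  fit_fe_clustered(sub, formula)
}

#' High-minus-low SES slope difference from stratified fits
#'
#' For each polygenic-index term present in both stratified fits, reports
#' the high-SES minus low-SES slope with standard error
#' `sqrt(se_high^2 + se_low^2)` (independent strata), normal-approximation
#' confidence interval and p value. A positive difference means the index
#' is more predictive in high-SES families; a negative one is the
#' compensation pattern.
#'
#' @param fit_high,fit_low `fit_result`s from [fit_stratified_fe()].
#' @param terms terms to contrast; defaults to the polygenic-index terms.
#' @param level confidence level.
#' @return data frame of class `slope_difference`.
#' @export
diff_stratified <- function(fit_high, fit_low, terms = NULL, level = 0.95) {
  common <- intersect(names(fit_high$coef), names(fit_low$coef))
  if (is.null(terms)) terms <- grep("^pgi_", common, value = TRUE)
  terms <- intersect(terms, common)
  if (!length(terms)) contract_error("no common terms to contrast")
  diff <- fit_high$coef[terms] - fit_low$coef[terms]
  se <- sqrt(fit_high$se[terms]^2 + fit_low$se[terms]^2)
  z <- diff / se
  p <- 2 * stats::pnorm(-abs(z))
  qz <- stats::qnorm(1 - (1 - level) / 2)
  out <- data.frame(term = terms, diff = unname(diff), se = unname(se),
                    ci_lo = unname(diff - qz * se),
                    ci_hi = unname(diff + qz * se),
                    z = unname(z), p = unname(p),
                    stringsAsFactors = FALSE)
  class(out) <- c("slope_difference", "data.frame")
  out
}

#' Logistic regression with family-clustered standard errors
#'
#' Maximum-likelihood logit with the clustered sandwich covariance
#' (robustness specification for the binary outcomes).
#'
#' @inheritParams fit_linear_clustered
#' @return a `fit_result`.
#' @export
fit_logit_clustered <- function(sample, formula) {
  pr <- prepare_xy(sample, formula)
  if (!is_binary01(pr$y))
    contract_error("logistic fit requires a binary 0/1 outcome")
  dc <- drop_collinear(pr$X)
  X <- dc$X
  G <- length(unique(pr$cluster))
  fit <- suppressWarnings(
    stats::glm.fit(X, pr$y, family = stats::binomial()))
  mu <- fit$fitted.values
  if (!fit$converged || any(mu > 1 - 1e-10) || any(mu < 1e-10))
    gxe_stop("gxefam_divergence_error",
             "logistic fit did not converge (possible perfect separation)")
  w <- mu * (1 - mu)
  info <- crossprod(X * sqrt(w))
  bread <- chol2inv(chol(info))
  S <- rowsum(X * (pr$y - mu), pr$cluster)
  V <- G / (G - 1) * bread %*% crossprod(S) %*% bread
  dimnames(V) <- list(colnames(X), colnames(X))
  beta <- fit$coefficients
  new_fit_result(beta, V, df = G - 1L, n_obs = nrow(X), n_clusters = G,
                 estimator = "logit", formula = formula,
                 dropped = dc$dropped, term_map = pr$term_map,
                 x_means = colMeans(X))
}
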