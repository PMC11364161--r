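# Multiple-testing control for the seven-outcome test family of one
# (polygenic index, design) pair: Bonferroni and Romano-Wolf step-down
# maxT adjustment under a family-cluster pairs bootstrap.

#' Bonferroni adjustment for a family of up to seven tests
#'
#' Adjusted p values are `min(1, m * p)`; a test is significant when its raw
#' p value is below `alpha / m` (with the default seven outcomes at
#' familywise 0.05, the per-test threshold 0.05/7, printed to three decimals
#' as 0.007).
#'
#' @param pvals numeric vector of raw p values (1 to 7).
#' @param alpha familywise level.
#' @return list with `p_raw`, `p_adj`, `sig`, the per-test `threshold`,
#'   `m` and `alpha`.
#' @export
bonferroni_adjust <- function(pvals, alpha = 0.05) {
  if (any(is.na(pvals)) || any(pvals < 0 | pvals > 1))
    contract_error("p values must lie in [0, 1]")
  m <- length(pvals)
  if (m < 1 || m > 7)
    contract_error("the test family holds between 1 and 7 outcomes")
  list(p_raw = pvals, p_adj = pmin(1, m * pvals),
       sig = pvals < alpha / m, threshold = alpha / m, m = m, alpha = alpha)
}

# ---- hypothesis plumbing --------------------------------------------------

# One hypothesis = one (sample, formula, focal term). For between/trio the
# statistic is the focal interaction coefficient; for the within design it
# is the high-minus-low SES stratified slope difference of the focal index.
make_hypothesis <- function(sample, formula, term,
                            type = c("coef", "strat_diff")) {
  list(sample = sample, formula = formula, term = term,
       type = match.arg(type))
}

#' Build the seven-outcome interaction hypothesis family
#'
#' For one design and focal polygenic index, constructs per outcome the
#' design sample (seeded per design and outcome), the model and the tested
#' term: the focal-index-by-SES interaction coefficient in the fully
#' interacted model (between, trio) or the SES-stratified slope difference
#' of the focal index (within).
#'
#' @param cohort a `cohort`.
#' @param design `"between"`, `"within"` or `"trio"`.
#' @param focal_pgi `"cog"` or `"noncog"`.
#' @param outcomes outcome names (default all seven).
#' @param seed master seed for the sample-selection draws.
#' @return named list of hypotheses.
#' @export
interaction_hypotheses <- function(cohort, design, focal_pgi,
                                   outcomes = names(outcome_columns()),
                                   seed = 1L) {
  focal <- paste0("pgi_", focal_pgi)
  hyps <- lapply(outcomes, function(o) {
    smp <- build_sample(cohort, design, o, seed)
    if (design == "within") {
      make_hypothesis(smp, expand_baseline("within", o), focal, "strat_diff")
    } else {
      make_hypothesis(smp, expand_interacted(design, o, focal_pgi),
                      paste0(focal, ":ses"), "coef")
    }
  })
  names(hyps) <- outcomes
  hyps
}

# fast least-squares estimate and clustered se of one column
fast_ols_term <- function(X, y, cluster_int, j, k_absorbed = 0L) {
  XtX <- crossprod(X)
  R <- tryCatch(chol(XtX), error = function(e) NULL)
  if (is.null(R)) return(NULL)
  bread <- chol2inv(R)
  beta <- drop(bread %*% crossprod(X, y))
  e <- y - drop(X %*% beta)
  G <- length(unique(cluster_int))
  N <- nrow(X); K <- ncol(X) + k_absorbed
  if (G < 2 || N <= K) return(NULL)
  S <- rowsum(X * e, cluster_int)
  u <- drop(S %*% bread[, j])
  v <- G / (G - 1) * (N - 1) / (N - K) * sum(u^2)
  if (!is.finite(v) || v <= 0) return(NULL)
  c(est = beta[j], se = sqrt(v))
}

# precompute the bootstrap-ready representation of one hypothesis
prep_hypothesis <- function(h) {
  if (h$type == "coef") {
    fit0 <- fit_linear_clustered(h$sample, h$formula)
    if (!h$term %in% names(fit0$coef))
      schema_error(sprintf("term '%s' not estimable in the model", h$term))
    pr <- prepare_xy(h$sample, h$formula)
    keep <- names(fit0$coef)
    X <- pr$X[, keep, drop = FALSE]
    fam <- pr$cluster
    list(type = "coef", X = X, y = pr$y, fam = fam,
         byfam = split(seq_along(fam), fam),
         j = match(h$term, keep),
         est0 = unname(fit0$coef[h$term]), se0 = unname(fit0$se[h$term]),
         p_raw = unname(fit0$p[h$term]), n = fit0$n_obs,
         n_clusters = fit0$n_clusters, fits = list(fit = fit0))
  } else {
    fit_lo <- fit_stratified_fe(h$sample, h$formula, 0)
    fit_hi <- fit_stratified_fe(h$sample, h$formula, 1)
    dd <- diff_stratified(fit_hi, fit_lo, terms = h$term)
    pr <- prepare_xy(h$sample, h$formula, intercept = FALSE)
    fam <- pr$cluster
    demean <- function(M) M - rowsum(M, fam)[fam, , drop = FALSE] /
      as.vector(table(fam)[fam])
    Xd <- demean(pr$X)
    yd <- drop(demean(matrix(pr$y)))
    fam_ses <- tapply(h$sample$data$ses, h$sample$data$family_id, max)
    cols <- list(`0` = names(fit_lo$coef), `1` = names(fit_hi$coef))
    list(type = "strat_diff", Xd = Xd, yd = yd, fam = fam,
         byfam = split(seq_along(fam), fam), fam_ses = fam_ses,
         cols = cols, term = h$term,
         est0 = dd$diff, se0 = dd$se, p_raw = dd$p,
         n = nrow(Xd), n_clusters = length(unique(fam)),
         fits = list(high = fit_hi, low = fit_lo, diff = dd))
  }
}

# one bootstrap evaluation of a prepared hypothesis for a family draw;
# returns c(est, se) or NULL when the refit is unusable
boot_eval <- function(ph, drawn) {
  idx <- ph$byfam[drawn]
  len <- lengths(idx)
  rows <- unlist(idx, use.names = FALSE)
  if (is.null(rows) || length(rows) == 0) return(NULL)
  cl <- rep(seq_along(drawn), len)
  if (ph$type == "coef") {
    fast_ols_term(ph$X[rows, , drop = FALSE], ph$y[rows], cl, ph$j)
  } else {
    ses_d <- ph$fam_ses[drawn]
    ses_vals <- c(0, 1)
    est <- se2 <- 0
    for (s in 1:2) {
      in_s <- ses_d == ses_vals[s] & len > 0
      if (sum(in_s) < 2) return(NULL)
      rows_s <- unlist(idx[in_s], use.names = FALSE)
      cl_s <- rep(seq_along(drawn)[in_s], len[in_s])
      cols <- ph$cols[[as.character(ses_vals[s])]]
      if (!ph$term %in% cols) return(NULL)
      Xs <- ph$Xd[rows_s, cols, drop = FALSE]
      G_s <- sum(in_s)
      r <- fast_ols_term(Xs, ph$yd[rows_s], cl_s, match(ph$term, cols),
                         k_absorbed = G_s)
      if (is.null(r)) return(NULL)
      est <- est + (if (s == 2) r["est"] else -r["est"])
      se2 <- se2 + r["se"]^2
    }
    c(est = unname(est), se = sqrt(unname(se2)))
  }
}

#' Romano-Wolf step-down adjustment by family-cluster bootstrap
#'
#' Step-down maxT adjustment: families are resampled with replacement from
#' the union of families underlying all hypotheses (one joint draw per
#' iteration, preserving cross-outcome dependence); each hypothesis's design
#' sample is rebuilt from the resample — selection rules are family-local,
#' so a resampled family re-enters each sample exactly as its original
#' selection — the model is refitted, and recentred studentised statistics
#' `(est* - est) / se*` feed the step-down max rule with enforced
#' monotonicity. Adjusted p values use the `(1 + count) / (B + 1)`
#' convention. Bootstrap refits that are singular are redrawn up to
#' `max_redraw` times (the count is reported); exceeding the cap is an
#' instability error.
#'
#' @param hypotheses list from [interaction_hypotheses()] (or
#'   `make_hypothesis`-style entries), all built from one cohort.
#' @param B bootstrap replications (>= 100).
#' @param seed seed for the resampling stream.
#' @param alpha familywise level used for the significance flags.
#' @param max_redraw cap on redrawn singular iterations.
#' @return object of class `correction_result`: a per-outcome table with raw,
#'   Bonferroni- and Romano-Wolf-adjusted p values.
#' @export
romano_wolf_adjust <- function(hypotheses, B = 1000, seed = 1L,
                               alpha = 0.05, max_redraw = B) {
  if (length(hypotheses) < 1) contract_error("need at least one hypothesis")
  if (B < 100) contract_error("B must be at least 100")
  preps <- lapply(hypotheses, prep_hypothesis)
  names(preps) <- names(hypotheses)
  romano_wolf_core(preps, B = B, seed = seed, alpha = alpha,
                   max_redraw = max_redraw)
}

# step-down maxT over already-prepared hypotheses
romano_wolf_core <- function(preps, B, seed, alpha, max_redraw = B) {
  K <- length(preps)
  fam_union <- unique(unlist(lapply(preps, function(p) names(p$byfam)),
                             use.names = FALSE))
  nf <- length(fam_union)
  t0 <- vapply(preps, function(p) p$est0 / p$se0, 0)
  set.seed(subseed(seed, "romano-wolf"))
  tstar <- matrix(NA_real_, K, B)
  n_redraw <- 0L
  b <- 1L
  while (b <= B) {
    drawn <- fam_union[sample.int(nf, nf, replace = TRUE)]
    res <- lapply(preps, boot_eval, drawn = drawn)
    if (any(vapply(res, is.null, TRUE))) {
      n_redraw <- n_redraw + 1L
      if (n_redraw > max_redraw)
        gxe_stop("gxefam_instability_error",
                 sprintf("more than %d singular bootstrap refits", max_redraw))
      next
    }
    tstar[, b] <- vapply(seq_len(K), function(k)
      (res[[k]]["est"] - preps[[k]]$est0) / res[[k]]["se"], 0)
    b <- b + 1L
  }
  # step-down max rule over hypotheses ordered by |t| descending
  ord <- order(-abs(t0))
  A <- abs(tstar[ord, , drop = FALSE])
  Mx <- apply(A, 2, function(col) rev(cummax(rev(col))))
  Mx <- matrix(Mx, nrow = K)
  p_rw_ord <- vapply(seq_len(K), function(j)
    (1 + sum(Mx[j, ] >= abs(t0[ord[j]]))) / (B + 1), 0)
  p_raw <- vapply(preps, function(p) p$p_raw, 0)
  # enforce step-down monotonicity and adjusted >= raw
  p_rw_ord <- cummax(pmax(p_rw_ord, p_raw[ord]))
  p_rw <- numeric(K); p_rw[ord] <- p_rw_ord
  bonf <- bonferroni_adjust(p_raw, alpha)
  tab <- data.frame(
    outcome = names(preps) %||% as.character(seq_len(K)),
    estimate = vapply(preps, function(p) p$est0, 0),
    se = vapply(preps, function(p) p$se0, 0),
    t = unname(t0), n = vapply(preps, function(p) p$n, 0),
    n_clusters = vapply(preps, function(p) p$n_clusters, 0),
    p_raw = unname(p_raw), p_bonf = unname(bonf$p_adj),
    p_rw = p_rw,
    sig_raw = unname(p_raw) < alpha,
    sig_bonf = unname(bonf$sig),
    sig_rw = p_rw < alpha,
    stringsAsFactors = FALSE)
  structure(list(table = tab, alpha = alpha, B = B, seed = seed,
                 n_redraw = n_redraw, threshold_bonf = bonf$threshold,
                 fits = lapply(preps, `[[`, "fits")),
            class = "correction_result")
}

#' @export
print.correction_result <- function(x, ...) {
  cat(sprintf("<correction_result> B = %d, alpha = %.3g (Bonferroni per-test threshold %.4g)\n",
              x$B, x$alpha, x$threshold_bonf))
  print(x$table, digits = 3, row.names = FALSE)
  if (x$n_redraw > 0)
    cat(sprintf("  %d singular bootstrap iterations redrawn\n", x$n_redraw))
  invisible(x)
}
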