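# Power analysis for the gene-by-environment interaction term: analytic
# minimum detectable incremental R-squared via the noncentral F
# distribution, and Monte-Carlo post-hoc power over the full stage chain.

new_power_result <- function(mode, n, k_full, alpha, target_power = NA,
                             value, mc_se = NA, reps = NA, seed = NA,
                             extra = list()) {
  structure(c(list(mode = mode, n = n, k_full = k_full, alpha = alpha,
                   target_power = target_power, value = value,
                   mc_se = mc_se, reps = reps, seed = seed), extra),
            class = "power_result")
}

#' @export
print.power_result <- function(x, ...) {
  if (x$mode == "analytic") {
    cat(sprintf(
      "<power_result> analytic: min detectable incremental R^2 = %.6g\n  (n = %d, k_full = %d, alpha = %.3g, power = %.2f)\n",
      x$value, x$n, x$k_full, x$alpha, x$target_power))
  } else {
    cat(sprintf(
      "<power_result> Monte-Carlo: rejection rate = %.3f +/- %.3f (MC SE)\n  (reps = %d, alpha = %.3g)\n",
      x$value, x$mc_se, x$reps, x$alpha))
    cat("  note: uses the generating effect sizes, not estimated ones;\n",
        " post-hoc power from observed effects is not fully informative.\n")
  }
  invisible(x)
}

# power of the 1-numerator-df incremental F test at incremental R^2 = d,
# with noncentrality n * f^2, f^2 = d / (1 - (r2_base + d))
incremental_f_power <- function(d, n, k_full, alpha, r2_base = 0) {
  df2 <- n - k_full - 1
  f2 <- d / (1 - (r2_base + d))
  ncp <- n * f2
  crit <- stats::qf(1 - alpha, 1, df2)
  1 - stats::pf(crit, 1, df2, ncp = ncp)
}

#' Minimum detectable incremental R-squared for the interaction term
#'
#' The smallest incremental R-squared such that the one-degree-of-freedom
#' incremental F test (one additional tested covariate — the interaction
#' term — on top of `k_full - 1` other slopes) reaches the target power at
#' level `alpha`, found by root-finding on the noncentral-F power curve with
#' noncentrality `n * f^2`, `f^2 = dR2 / (1 - R2_full)`.
#'
#' @param n sample size.
#' @param k_full slope count of the full (interacted) model, including the
#'   tested term.
#' @param alpha test level.
#' @param power target power.
#' @param r2_base explained variance of the model without the tested term.
#' @return a `power_result` with the minimum incremental R-squared.
#' @export
min_detectable_delta_r2 <- function(n, k_full, alpha = 0.05, power = 0.8,
                                    r2_base = 0) {
  if (n <= k_full + 1)
    gxe_stop("gxefam_infeasible_error",
             sprintf("n = %d leaves no residual degrees of freedom with k_full = %d",
                     n, k_full))
  if (power <= alpha)
    return(new_power_result("analytic", n, k_full, alpha, power, 0))
  f <- function(d) incremental_f_power(d, n, k_full, alpha, r2_base) - power
  upper <- 0.999 - r2_base
  if (f(upper) < 0)
    gxe_stop("gxefam_infeasible_error", "target power unattainable at this n")
  root <- stats::uniroot(f, c(1e-12, upper), tol = 1e-12)$root
  new_power_result("analytic", n, k_full, alpha, power, root)
}

#' Monte-Carlo post-hoc power for the focal interaction
#'
#' Simulates `reps` cohorts under the configured structural model, runs the
#' full stage chain (generate, select the design sample, expand the model,
#' fit with clustered errors) and reports the rejection rate of the focal
#' interaction at level `alpha` with its binomial Monte-Carlo standard
#' error. Uses the generating effect sizes from `config`, not estimated
#' ones. Failed replicate fits are counted; more than 10% failures is an
#' instability error.
#'
#' @param config a [cohort_config()].
#' @param design `"between"`, `"within"` or `"trio"`.
#' @param outcome outcome name.
#' @param focal_pgi `"cog"` or `"noncog"`.
#' @param reps number of simulated cohorts (>= 50).
#' @param alpha test level.
#' @param seed master seed; replicate r uses `subseed(seed, "mc-power", r)`.
#' @param record_delta_r2 also fit the non-interacted model per replicate
#'   and record the mean incremental R-squared of the focal term (between
#'   and trio designs).
#' @return a `power_result`.
#' @export
monte_carlo_power <- function(config, design, outcome, focal_pgi,
                              reps = 200, alpha = 0.05, seed = 1L,
                              record_delta_r2 = FALSE) {
  if (reps < 50) contract_error("reps must be at least 50")
  design <- match.arg(design, c("between", "within", "trio"))
  focal <- paste0("pgi_", focal_pgi)
  rejected <- logical(0); failed <- 0L
  dr2 <- r2_full <- r2_base <- ns <- numeric(0); k_full <- NA_integer_
  for (r in seq_len(reps)) {
    res <- tryCatch({
      cohort <- simulate_cohort(config, seed = subseed(seed, "mc-power", r))
      smp <- build_sample(cohort, design, outcome, seed = subseed(seed, "mc-power-sample", r))
      if (design == "within") {
        frm <- expand_baseline("within", outcome)
        dd <- diff_stratified(fit_stratified_fe(smp, frm, 1),
                              fit_stratified_fe(smp, frm, 0), terms = focal)
        list(p = dd$p, n = nrow(smp$data), k = NA_real_,
             r2f = NA_real_, r2b = NA_real_)
      } else {
        frm <- expand_interacted(design, outcome, focal_pgi)
        fit <- fit_linear_clustered(smp, frm)
        r2b <- NA_real_
        if (record_delta_r2) {
          frm0 <- frm
          frm0$terms <- Filter(function(tr)
            !identical(sort(tr$vars), sort(c(focal, "ses"))), frm0$terms)
          r2b <- fit_linear_clustered(smp, frm0)$r_squared
        }
        list(p = unname(fit$p[paste0(focal, ":ses")]), n = fit$n_obs,
             k = length(fit$coef) - 1, r2f = fit$r_squared, r2b = r2b)
      }
    }, error = function(e) NULL)
    if (is.null(res) || is.na(res$p)) { failed <- failed + 1L; next }
    rejected <- c(rejected, res$p < alpha)
    ns <- c(ns, res$n); k_full <- res$k
    if (record_delta_r2 && !is.na(res$r2b)) {
      r2_full <- c(r2_full, res$r2f); r2_base <- c(r2_base, res$r2b)
      dr2 <- c(dr2, res$r2f - res$r2b)
    }
  }
  if (failed > 0.1 * reps)
    gxe_stop("gxefam_instability_error",
             sprintf("%d of %d replicates failed", failed, reps))
  rate <- mean(rejected)
  new_power_result("monte-carlo", n = round(mean(ns)), k_full = k_full,
                   alpha = alpha, value = rate,
                   mc_se = sqrt(rate * (1 - rate) / length(rejected)),
                   reps = length(rejected), seed = seed,
                   extra = list(failed = failed,
                                mean_delta_r2 = if (length(dr2)) mean(dr2) else NA,
                                mean_r2_full = if (length(r2_full)) mean(r2_full) else NA,
                                mean_r2_base = if (length(r2_base)) mean(r2_base) else NA))
}
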