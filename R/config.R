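# Scenario configuration for the synthetic family cohort.

#' Default structural coefficients for the seven educational outcomes
#'
#' Each outcome has a latent linear model
#' \deqn{Y^* = \alpha + \beta_{cog} PGI_{cog} + \beta_{noncog} PGI_{noncog}
#'   + \beta_{ses} SES + \gamma_{cog} PGI_{cog} \times SES
#'   + \gamma_{noncog} PGI_{noncog} \times SES
#'   + \eta_{cog} \overline{PGI}^{parents}_{cog}
#'   + \eta_{noncog} \overline{PGI}^{parents}_{noncog} + u_{fam} + e,}
#' where \eqn{u_{fam}} is a family-shared normal deviate and \eqn{e}
#' individual noise. The `nurture_*` coefficients (\eqn{\eta}) put a direct
#' family-environment effect of the mid-parent polygenic index on the child
#' outcome; they are 0 by default and exist so that passive gene-environment
#' correlation bias can be switched on explicitly.
#'
#' Default magnitudes follow the scale of typical polygenic-index studies of
#' Dutch educational outcomes: grade effects of roughly 0.1-0.2 points per
#' standard deviation of the index on a 1-5 scale with overall grade standard
#' deviation near 0.9, test-score effects of roughly 0.1-0.2 standard
#' deviations, and interaction coefficients of -0.1 (cognitive) and -0.06
#' (noncognitive), i.e. a compensation-patterned scenario in which the index
#' is less predictive for high-SES children. Binary outcomes additionally
#' carry a target prevalence (0.5 for upper-track attendance, matching the
#' test-score recommendation boundary; 0.35 for higher-education attainment)
#' and the standard deviation of the threshold-specific noise.
#'
#' @param ... named per-outcome lists overriding any subset of fields, e.g.
#'   `default_effects(cito = list(gamma_cog = 0))`.
#' @return named list of per-outcome coefficient lists.
#' @export
default_effects <- function(...) {
  grade <- list(intercept = 3.5, beta_cog = 0.18, beta_noncog = 0.08,
                beta_ses = 0.25, gamma_cog = -0.10, gamma_noncog = -0.06,
                nurture_cog = 0, nurture_noncog = 0,
                family_sd = 0.35, noise_sd = 0.77)
  cito <- list(intercept = 0, beta_cog = 0.22, beta_noncog = 0.13,
               beta_ses = 0.40, gamma_cog = -0.10, gamma_noncog = -0.08,
               nurture_cog = 0, nurture_noncog = 0,
               family_sd = 0.55, noise_sd = 0.72)
  track <- list(intercept = 0, beta_cog = 0.28, beta_noncog = 0.18,
                beta_ses = 0.55, gamma_cog = -0.12, gamma_noncog = -0.10,
                nurture_cog = 0, nurture_noncog = 0,
                family_sd = 0.55, noise_sd = 0.72,
                prevalence = 0.50, threshold_noise_sd = 0.30)
  attain <- list(intercept = 0, beta_cog = 0.25, beta_noncog = 0.20,
                 beta_ses = 0.55, gamma_cog = -0.12, gamma_noncog = -0.10,
                 nurture_cog = 0, nurture_noncog = 0,
                 family_sd = 0.55, noise_sd = 0.72,
                 prevalence = 0.35, threshold_noise_sd = 0.30)
  eff <- list(math7 = grade, read7 = grade, math10 = grade, read10 = grade,
              cito = cito, track = track, attain = attain)
  dots <- list(...)
  for (nm in names(dots)) {
    if (!nm %in% names(eff))
      config_error(sprintf("unknown outcome '%s' in effects override", nm))
    eff[[nm]][names(dots[[nm]])] <- dots[[nm]]
  }
  eff
}

#' Scenario configuration for a synthetic family cohort
#'
#' Describes one simulated cohort: its size and family composition, the
#' genetic architecture behind the two polygenic indices, the strength of
#' passive gene-environment correlation, the socioeconomic-status base rate,
#' the per-outcome structural coefficients, and genotype missingness.
#'
#' The default sizes (2,500 families, family mix of 30% monozygotic pairs,
#' 40% dizygotic pairs, 15% monozygotic pair plus one sibling, 15% dizygotic
#' pair plus one sibling, 25% person-wise genotype missingness) yield
#' analytical samples near 3,700 children in the between-family design, about
#' 2,200 in the within-family design and about 2,000 in the trio design,
#' comparable to the age-7 mathematics-grade samples of large twin-register
#' studies. `n_multiplier` rescales the number of families in one step.
#'
#' @param n_families number of families.
#' @param n_loci number of unlinked biallelic loci behind the indices.
#' @param maf_low,maf_high bounds of the uniform allele-frequency draw,
#'   with `0 < maf_low <= maf_high <= 0.5`.
#' @param zygosity_mix named proportions over family types `mz`, `dz`,
#'   `mz_sib`, `dz_sib` (twin pair, optionally plus one full sibling);
#'   must sum to 1.
#' @param pgi_weights_scale dispersion of the per-locus weights of each index.
#' @param rge_strength coefficient of the parental polygenic indices on the
#'   parental-education propensity (>= 0); the passive gene-environment
#'   correlation dial.
#' @param ses_base_rate target share of high-SES families (strictly in (0,1)),
#'   where family SES is the highest of the two parents' education indicators.
#' @param effects per-outcome structural coefficients, see [default_effects()].
#' @param missing_genotype_rate probability in `[0, 1)` that a person's
#'   genotype (hence their measured polygenic indices) is unobserved.
#' @param structure_strength optional population-structure dial in `[0, 1)`:
#'   correlation of the first ancestry principal component with the person's
#'   mean allele dosage (0 = principal components are pure noise).
#' @param n_multiplier single multiplier applied to `n_families`.
#' @param seed master seed; all generator randomness derives from it via
#'   [subseed()].
#' @return object of class `cohort_config`.
#' @export
cohort_config <- function(n_families = 2500,
                          n_loci = 500,
                          maf_low = 0.05, maf_high = 0.5,
                          zygosity_mix = c(mz = 0.30, dz = 0.40,
                                           mz_sib = 0.15, dz_sib = 0.15),
                          pgi_weights_scale = 1,
                          rge_strength = 0.25,
                          ses_base_rate = 0.41,
                          effects = default_effects(),
                          missing_genotype_rate = 0.25,
                          structure_strength = 0,
                          n_multiplier = 1,
                          seed = 1L) {
  cfg <- structure(list(
    n_families = as.integer(round(n_families * n_multiplier)),
    n_loci = as.integer(n_loci),
    maf_low = maf_low, maf_high = maf_high,
    zygosity_mix = zygosity_mix,
    pgi_weights_scale = pgi_weights_scale,
    rge_strength = rge_strength,
    ses_base_rate = ses_base_rate,
    effects = effects,
    missing_genotype_rate = missing_genotype_rate,
    structure_strength = structure_strength,
    seed = as.integer(seed)
  ), class = "cohort_config")
  validate_config(cfg)
  cfg
}

#' @export
print.cohort_config <- function(x, ...) {
  cat("<cohort_config>\n")
  cat(sprintf("  families: %d   loci: %d   maf: [%.3g, %.3g]\n",
              x$n_families, x$n_loci, x$maf_low, x$maf_high))
  cat(sprintf("  zygosity mix: %s\n",
              paste(sprintf("%s=%.2f", names(x$zygosity_mix), x$zygosity_mix),
                    collapse = " ")))
  cat(sprintf("  rge_strength: %.3g   ses_base_rate: %.2f   missingness: %.2f\n",
              x$rge_strength, x$ses_base_rate, x$missing_genotype_rate))
  cat(sprintf("  seed: %d\n", x$seed))
  invisible(x)
}

validate_config <- function(cfg) {
  if (!inherits(cfg, "cohort_config")) config_error("not a cohort_config")
  with(cfg, {
    if (is.na(n_families) || n_families < 0)
      config_error("n_families must be a non-negative count")
    if (is.na(n_loci) || n_loci < 1)
      config_error("n_loci must be a positive count")
    if (!(maf_low > 0))
      config_error(sprintf("maf_low must be > 0 (got %g)", maf_low))
    if (!(maf_low <= maf_high))
      config_error(sprintf("maf_low (%g) must be <= maf_high (%g)",
                           maf_low, maf_high))
    if (!(maf_high <= 0.5))
      config_error(sprintf("maf_high must be <= 0.5 (got %g)", maf_high))
    if (is.null(names(zygosity_mix)) ||
        !all(names(zygosity_mix) %in% c("mz", "dz", "mz_sib", "dz_sib")))
      config_error("zygosity_mix must be named with mz, dz, mz_sib, dz_sib")
    if (any(zygosity_mix < 0))
      config_error("zygosity_mix proportions must be non-negative")
    if (abs(sum(zygosity_mix) - 1) > 1e-12)
      config_error(sprintf("zygosity_mix must sum to 1 (got %.15g)",
                           sum(zygosity_mix)))
    if (!(pgi_weights_scale > 0))
      config_error("pgi_weights_scale must be > 0")
    if (rge_strength < 0)
      config_error("rge_strength must be >= 0")
    if (!(ses_base_rate > 0 && ses_base_rate < 1))
      config_error(sprintf("ses_base_rate must be strictly in (0,1) (got %g)",
                           ses_base_rate))
    if (missing_genotype_rate < 0 || missing_genotype_rate >= 1)
      config_error("missing_genotype_rate must be in [0, 1)")
    if (structure_strength < 0 || structure_strength >= 1)
      config_error("structure_strength must be in [0, 1)")
    for (nm in names(effects)) {
      e <- effects[[nm]]
      num <- unlist(e[c("intercept", "beta_cog", "beta_noncog", "beta_ses",
                        "gamma_cog", "gamma_noncog",
                        "nurture_cog", "nurture_noncog")])
      if (any(!is.finite(num)))
        config_error(sprintf("non-finite structural coefficient for '%s'", nm))
      if (e$family_sd < 0 || e$noise_sd < 0)
        config_error(sprintf("sd parameters must be >= 0 for '%s'", nm))
      if (!is.null(e$prevalence) &&
          !(e$prevalence > 0 && e$prevalence < 1))
        config_error(sprintf("prevalence must be in (0,1) for '%s'", nm))
    }
  })
  invisible(cfg)
}
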