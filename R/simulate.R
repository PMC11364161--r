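# Synthetic family-cohort generator: parents, meiosis, polygenic indices,
# socioeconomic status with passive gene-environment correlation, and the
# seven educational outcomes.

# Frozen calibration constants for the observed outcome scales.
# The end-of-primary test score is drawn as an affine map of the standardised
# latent outcome, rounded to integers and censored to its printed 501-550
# range; the pre-censoring location/scale below are chosen once so that the
# censored score has mean 538.9 and standard deviation 9.
CITO_MU    <- 539.8078
CITO_SIGMA <- 10.43682
CITO_MIN   <- 501
CITO_MAX   <- 550
# Grades are the latent outcome rounded to the nearest integer and clipped to
# the 1-5 scale, i.e. fixed cut-points at 1.5, 2.5, 3.5 and 4.5; with the
# default latent scale this yields a grade standard deviation near 0.9.
GRADE_MIN <- 1
GRADE_MAX <- 5

SCHEMA_VERSION <- "1"

person_schema <- function() {
  c("person_id", "family_id", "role", "zygosity", "geno_missing",
    "pgi_cog", "pgi_noncog", "pgi_cog_true", "pgi_noncog_true",
    "pgi_cog_f", "pgi_cog_m", "pgi_noncog_f", "pgi_noncog_m",
    "educ_father", "educ_mother", "ses",
    paste0("pc", 1:10), "platform",
    "math7", "read7", "math10", "read10",
    "cito_raw", "cito_z", "track", "attain")
}

empty_individuals <- function() {
  cols <- person_schema()
  out <- as.data.frame(setNames(rep(list(logical(0)), length(cols)), cols))
  out$person_id <- character(0); out$family_id <- character(0)
  out$role <- character(0); out$zygosity <- character(0)
  out$platform <- character(0)
  for (cc in setdiff(cols, c("person_id", "family_id", "role", "zygosity",
                             "platform", "geno_missing")))
    out[[cc]] <- numeric(0)
  out
}

new_cohort <- function(individuals, geno, maf, config,
                       pgi_weights = NULL) {
  structure(list(individuals = individuals, geno = geno, maf = maf,
                 pgi_weights = pgi_weights, config = config,
                 schema_version = SCHEMA_VERSION),
            class = "cohort")
}

#' @export
print.cohort <- function(x, ...) {
  ind <- x$individuals
  nfam <- length(unique(ind$family_id))
  cat(sprintf("<cohort> %d individuals in %d families", nrow(ind), nfam))
  if (!is.null(x$geno)) cat(sprintf(", %d loci", ncol(x$geno)))
  cat("\n")
  if (nrow(ind)) {
    cat("  roles: ", paste(sprintf("%s=%d", names(table(ind$role)),
                                   table(ind$role)), collapse = " "), "\n")
    cat(sprintf("  genotype missing: %.1f%%   outcomes present: %s\n",
                100 * mean(ind$geno_missing),
                paste(names(outcome_columns())[
                  vapply(outcome_columns(),
                         function(cc) any(!is.na(ind[[cc]])), TRUE)],
                  collapse = " ")))
  }
  invisible(x)
}

family_ids <- function(n) sprintf("F%05d", seq_len(n))

#' Simulate the parent generation
#'
#' Draws, for each family, a father and a mother with independent genotypes:
#' per-locus allele frequencies are uniform on `[maf_low, maf_high]` (one
#' draw per locus, shared by the whole cohort) and dosages are
#' binomial(2, p_l). Loci are unlinked. Person-wise genotype-missingness
#' flags are assigned here too, so that downstream trio filtering sees
#' ungenotyped parents.
#'
#' @param config a [cohort_config()].
#' @return a `cohort` containing only parent rows (outcome and index columns
#'   still empty).
#' @export
simulate_parents <- function(config) {
  validate_config(config)
  L <- config$n_loci; nf <- config$n_families
  set.seed(subseed(config$seed, "parents"))
  maf <- stats::runif(L, config$maf_low, config$maf_high)
  if (nf == 0) {
    return(new_cohort(empty_individuals(),
                      matrix(integer(0), 0, L,
                             dimnames = list(NULL, paste0("g", seq_len(L)))),
                      maf, config))
  }
  fam <- family_ids(nf)
  np <- 2L * nf
  geno <- matrix(stats::rbinom(np * L, 2L, rep(maf, each = np)),
                 nrow = np, ncol = L,
                 dimnames = list(NULL, paste0("g", seq_len(L))))
  ind <- empty_individuals()[rep(1, 0), ]
  ind <- data.frame(
    person_id = paste0(rep(fam, each = 2L), "_", rep(PARENT_ROLES, nf)),
    family_id = rep(fam, each = 2L),
    role = rep(PARENT_ROLES, nf),
    zygosity = "not-twin",
    geno_missing = as.logical(
      stats::rbinom(np, 1L, config$missing_genotype_rate)),
    stringsAsFactors = FALSE)
  for (cc in setdiff(person_schema(), names(ind))) ind[[cc]] <- NA
  ind$platform <- NA_character_
  rownames(geno) <- ind$person_id
  new_cohort(ind[, person_schema()], geno, maf, config)
}

#' Simulate meiosis: children of the parent generation
#'
#' Draws each family's child composition from `zygosity_mix` (a twin pair,
#' optionally plus one full sibling), then transmits, independently per
#' locus, one random allele from each parent to each non-monozygotic child;
#' a monozygotic pair is one meiosis duplicated, so co-twins have identical
#' genotypes. Children are flagged genotype-missing person-wise with
#' probability `missing_genotype_rate`.
#'
#' @param parents cohort fragment from [simulate_parents()].
#' @param config a [cohort_config()].
#' @return a `cohort` with parent and child rows.
#' @export
meiose_children <- function(parents, config) {
  validate_config(config)
  ind <- parents$individuals
  if (nrow(ind) == 0) return(parents)
  fams <- unique(ind$family_id)
  per_fam <- table(factor(ind$role[ind$role %in% PARENT_ROLES],
                          levels = PARENT_ROLES),
                   ind$family_id[ind$role %in% PARENT_ROLES])
  if (any(per_fam != 1))
    structure_error("every family needs exactly one father and one mother")
  nf <- length(fams)
  L <- config$n_loci

  set.seed(subseed(config$seed, "composition"))
  ftype <- sample(names(config$zygosity_mix), nf, replace = TRUE,
                  prob = config$zygosity_mix)

  # child roster: twins always, one sibling for *_sib types
  n_child <- ifelse(grepl("sib", ftype), 3L, 2L)
  child_fam <- rep(fams, n_child)
  child_role <- unlist(lapply(n_child, function(k) CHILD_ROLES[seq_len(k)]),
                       use.names = FALSE)
  zyg_type <- rep(ifelse(grepl("^mz", ftype), "MZ", "DZ"), n_child)
  child_zyg <- ifelse(child_role == "sibling", "not-twin", zyg_type)
  nc <- length(child_fam)

  fa_idx <- match(paste0(child_fam, "_father"), ind$person_id)
  mo_idx <- match(paste0(child_fam, "_mother"), ind$person_id)

  set.seed(subseed(config$seed, "meiosis"))
  # one random allele from each parent per locus; MZ twin2 copies twin1
  pf <- parents$geno[fa_idx, , drop = FALSE] / 2
  pm <- parents$geno[mo_idx, , drop = FALSE] / 2
  tf <- matrix(stats::rbinom(nc * L, 1L, pf), nc, L)
  tm <- matrix(stats::rbinom(nc * L, 1L, pm), nc, L)
  geno_c <- tf + tm
  mz2 <- which(child_role == "twin2" & child_zyg == "MZ")
  if (length(mz2)) {
    mz1 <- match(paste0(child_fam[mz2], "_twin1"),
                 paste0(child_fam, "_", child_role))
    geno_c[mz2, ] <- geno_c[mz1, , drop = FALSE]
  }
  colnames(geno_c) <- colnames(parents$geno)

  set.seed(subseed(config$seed, "missingness"))
  miss <- as.logical(stats::rbinom(nc, 1L, config$missing_genotype_rate))

  child <- data.frame(
    person_id = paste0(child_fam, "_", child_role),
    family_id = child_fam, role = child_role, zygosity = child_zyg,
    geno_missing = miss, stringsAsFactors = FALSE)
  for (cc in setdiff(person_schema(), names(child))) child[[cc]] <- NA
  child$platform <- NA_character_
  child <- child[, person_schema()]

  all_ind <- rbind(ind, child)
  ord <- order(all_ind$family_id,
               match(all_ind$role, c(PARENT_ROLES, CHILD_ROLES)))
  all_ind <- all_ind[ord, ]
  geno <- rbind(parents$geno, geno_c)
  rownames(geno) <- c(ind$person_id, child$person_id)
  geno <- geno[all_ind$person_id, , drop = FALSE]
  new_cohort(all_ind, geno, parents$maf, config, parents$pgi_weights)
}

#' Compute and standardise the two polygenic indices
#'
#' Each index is a fixed weighted sum of allele dosages; the two weight
#' vectors are drawn once per scenario from independent zero-mean normals
#' with scale `pgi_weights_scale`, then scores are z-standardised against
#' the genotyped-children reference set. Individuals flagged
#' genotype-missing keep their true (latent) index internally -- their
#' genetics exist regardless of measurement -- but their observed `pgi_*`
#' columns are missing. Parental observed indices are attached to each
#' child row (`pgi_cog_f`, `pgi_cog_m`, ...), which is what the trio design
#' conditions on.
#'
#' @param cohort cohort with genotypes.
#' @param config a [cohort_config()].
#' @return the cohort with index columns filled.
#' @export
compute_pgis <- function(cohort, config) {
  validate_config(config)
  ind <- cohort$individuals
  if (nrow(ind) == 0) return(cohort)
  if (is.null(cohort$pgi_weights)) {
    set.seed(subseed(config$seed, "weights"))
    W <- matrix(stats::rnorm(2L * config$n_loci, 0, config$pgi_weights_scale),
                ncol = 2, dimnames = list(NULL, c("cog", "noncog")))
    cohort$pgi_weights <- W
  }
  W <- cohort$pgi_weights
  if (any(colSums(W != 0) == 0) || any(apply(W, 2, stats::sd) == 0))
    degenerate_error("degenerate polygenic-index weights: zero variance, z-scoring undefined")
  raw <- cohort$geno %*% W
  ref <- ind$role %in% CHILD_ROLES & !ind$geno_missing
  if (sum(ref) < 2)
    degenerate_error("fewer than two genotyped children: standardisation undefined")
  mu <- colMeans(raw[ref, , drop = FALSE])
  sg <- apply(raw[ref, , drop = FALSE], 2, stats::sd)
  if (any(sg == 0))
    degenerate_error("polygenic scores constant over the reference set")
  z <- sweep(sweep(raw, 2, mu), 2, sg, "/")
  ind$pgi_cog_true <- z[, "cog"]; ind$pgi_noncog_true <- z[, "noncog"]
  ind$pgi_cog    <- ifelse(ind$geno_missing, NA_real_, z[, "cog"])
  ind$pgi_noncog <- ifelse(ind$geno_missing, NA_real_, z[, "noncog"])
  # attach observed parental indices to child rows
  is_child <- ind$role %in% CHILD_ROLES
  fa <- match(paste0(ind$family_id, "_father"), ind$person_id)
  mo <- match(paste0(ind$family_id, "_mother"), ind$person_id)
  ind$pgi_cog_f[is_child]    <- ind$pgi_cog[fa][is_child]
  ind$pgi_cog_m[is_child]    <- ind$pgi_cog[mo][is_child]
  ind$pgi_noncog_f[is_child] <- ind$pgi_noncog[fa][is_child]
  ind$pgi_noncog_m[is_child] <- ind$pgi_noncog[mo][is_child]
  cohort$individuals <- ind
  cohort
}

#' Assign parental education and family socioeconomic status
#'
#' Each parent's education propensity is
#' `rge_strength * (pgi_cog + pgi_noncog)/sqrt(2)` plus standard-normal
#' noise (their true indices: education predates genotyping). The propensity
#' is thresholded so that, under the dominance rule
#' `ses = max(educ_father, educ_mother)`, the expected share of high-SES
#' families equals `ses_base_rate`. With `rge_strength > 0` this creates
#' passive gene-environment correlation: children's indices correlate with
#' the family environment because parents transmit both.
#'
#' @param cohort cohort with parental indices computed.
#' @param config a [cohort_config()].
#' @return the cohort with `educ_father`, `educ_mother` and `ses` filled.
#' @export
assign_ses <- function(cohort, config) {
  validate_config(config)
  ind <- cohort$individuals
  if (nrow(ind) == 0) return(cohort)
  if (all(is.na(ind$pgi_cog_true)))
    structure_error("parental indices must be computed before assigning SES")
  set.seed(subseed(config$seed, "ses"))
  is_par <- ind$role %in% PARENT_ROLES
  prop <- config$rge_strength *
    (ind$pgi_cog_true[is_par] + ind$pgi_noncog_true[is_par]) / sqrt(2) +
    stats::rnorm(sum(is_par))
  # dominance rule: P(max of two parents = 1) = base rate
  q <- 1 - sqrt(1 - config$ses_base_rate)
  thr <- mean(prop) + stats::sd(prop) * stats::qnorm(1 - q)
  educ <- as.integer(prop > thr)
  par_fam <- ind$family_id[is_par]
  par_role <- ind$role[is_par]
  fams <- unique(ind$family_id)
  ef <- educ[match(paste0(fams, "_father"), paste0(par_fam, "_", par_role))]
  em <- educ[match(paste0(fams, "_mother"), paste0(par_fam, "_", par_role))]
  fi <- match(ind$family_id, fams)
  ind$educ_father <- ef[fi]
  ind$educ_mother <- em[fi]
  ind$ses <- pmax(ind$educ_father, ind$educ_mother)
  cohort$individuals <- ind
  cohort
}

#' Generate the seven educational outcomes and control variables
#'
#' For each outcome a latent child-level linear model (see
#' [default_effects()]) is drawn with a family-shared component and
#' individual noise, then mapped to the observed scale: grades are rounded
#' to the 1-5 scale, the standardised test score is an affine map of the
#' standardised latent calibrated to the printed mean 538.9 and standard
#' deviation 9 and censored to 501-550 (with an empirical z-score column),
#' and the binary outcomes threshold the standardised latent plus
#' threshold-specific noise at cuts calibrated to the configured
#' prevalences. Ancestry principal-component stand-ins and the genotyping
#' platform indicator are generated here: standard normal and a family-level
#' two-level factor, independent of genotype unless `structure_strength > 0`,
#' in which case the first component is tilted towards mean allele dosage.
#'
#' @param cohort cohort with indices and SES assigned.
#' @param config a [cohort_config()].
#' @return the cohort with outcome, principal-component and platform columns
#'   filled (outcomes for children only).
#' @export
generate_outcomes <- function(cohort, config) {
  validate_config(config)
  ind <- cohort$individuals
  if (nrow(ind) == 0) return(cohort)
  if (all(is.na(ind$ses))) structure_error("SES must be assigned first")
  set.seed(subseed(config$seed, "outcomes"))
  n <- nrow(ind)
  is_child <- ind$role %in% CHILD_ROLES
  nc <- sum(is_child)
  fams <- unique(ind$family_id)
  fi_child <- match(ind$family_id[is_child], fams)

  # controls
  pcs <- matrix(stats::rnorm(n * 10), n, 10)
  if (config$structure_strength > 0) {
    s <- config$structure_strength
    anc <- as.numeric(scale(rowMeans(cohort$geno)))
    pcs[, 1] <- sqrt(1 - s^2) * pcs[, 1] + s * anc
  }
  for (k in 1:10) ind[[paste0("pc", k)]] <- pcs[, k]
  plat_f <- sample(c("A", "B"), length(fams), replace = TRUE)
  ind$platform <- plat_f[match(ind$family_id, fams)]

  midp_cog <- (ind$pgi_cog_true[match(paste0(ind$family_id, "_father"),
                                      ind$person_id)] +
               ind$pgi_cog_true[match(paste0(ind$family_id, "_mother"),
                                      ind$person_id)]) / 2
  midp_non <- (ind$pgi_noncog_true[match(paste0(ind$family_id, "_father"),
                                         ind$person_id)] +
               ind$pgi_noncog_true[match(paste0(ind$family_id, "_mother"),
                                         ind$person_id)]) / 2

  latent_for <- function(e) {
    u_fam <- stats::rnorm(length(fams), 0, e$family_sd)[fi_child]
    eps <- stats::rnorm(nc, 0, e$noise_sd)
    with(ind[is_child, ],
         e$intercept + e$beta_cog * pgi_cog_true +
           e$beta_noncog * pgi_noncog_true + e$beta_ses * ses +
           e$gamma_cog * pgi_cog_true * ses +
           e$gamma_noncog * pgi_noncog_true * ses) +
      e$nurture_cog * midp_cog[is_child] +
      e$nurture_noncog * midp_non[is_child] +
      u_fam + eps
  }
  std <- function(x) (x - mean(x)) / stats::sd(x)

  for (o in c("math7", "read7", "math10", "read10")) {
    y <- latent_for(config$effects[[o]])
    ind[[o]][is_child] <- pmin(pmax(round(y), GRADE_MIN), GRADE_MAX)
  }
  yc <- std(latent_for(config$effects$cito))
  craw <- round(pmin(pmax(CITO_MU + CITO_SIGMA * yc, CITO_MIN), CITO_MAX))
  ind$cito_raw[is_child] <- craw
  ind$cito_z[is_child] <- std(craw)
  for (o in binary_outcomes()) {
    e <- config$effects[[o]]
    u <- std(latent_for(e)) + stats::rnorm(nc, 0, e$threshold_noise_sd)
    cut <- mean(u) + stats::sd(u) * stats::qnorm(1 - e$prevalence)
    ind[[o]][is_child] <- as.integer(u > cut)
  }
  cohort$individuals <- ind
  cohort
}

#' Simulate a complete family cohort
#'
#' Runs the full generator chain: parents, meiosis, polygenic indices,
#' socioeconomic status, outcomes. Identical configurations (including the
#' seed) produce bit-identical cohorts.
#'
#' @param config a [cohort_config()].
#' @param seed optional override of `config$seed`.
#' @return a `cohort`.
#' @export
#' @examples
#' cohort <- simulate_cohort(cohort_config(n_families = 50, n_loci = 50))
#' cohort
simulate_cohort <- function(config = cohort_config(), seed = NULL) {
  if (!is.null(seed)) config$seed <- as.integer(seed)
  validate_config(config)
  cohort <- simulate_parents(config)
  cohort <- meiose_children(cohort, config)
  cohort <- compute_pgis(cohort, config)
  cohort <- assign_ses(cohort, config)
  generate_outcomes(cohort, config)
}

#' Check Mendelian consistency of a cohort
#'
#' Asserts that at every locus each child's dosage can be decomposed into
#' one allele carried by the father and one by the mother.
#'
#' @param cohort a `cohort` with genotypes.
#' @return `TRUE` invisibly; otherwise a structural error.
#' @export
check_mendelian <- function(cohort) {
  ind <- cohort$individuals
  is_child <- ind$role %in% CHILD_ROLES
  if (!any(is_child)) return(invisible(TRUE))
  g <- cohort$geno
  gc <- g[ind$person_id[is_child], , drop = FALSE]
  gf <- g[paste0(ind$family_id[is_child], "_father"), , drop = FALSE]
  gm <- g[paste0(ind$family_id[is_child], "_mother"), , drop = FALSE]
  lo <- (gf == 2) + (gm == 2)
  hi <- (gf >= 1) + (gm >= 1)
  if (any(gc < lo | gc > hi))
    structure_error("Mendelian inconsistency: child allele not carried by a parent")
  invisible(TRUE)
}
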