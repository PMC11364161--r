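# Fixture builders shared across test files. All fixtures are generated in
# code; nothing is read from disk.

child_roles <- c("twin1", "twin2", "sibling")

# small default scenario used where only structure matters
small_config <- function(...) {
  cohort_config(n_families = 120, n_loci = 60, seed = 11, ...)
}

# hand-built cohort from a minimal per-person table; fills schema defaults
# so sample builders and estimators accept it (no genotypes needed)
manual_cohort <- function(df) {
  full <- df
  schema <- gxefam:::person_schema()
  for (cc in setdiff(schema, names(full))) full[[cc]] <- NA
  if (all(is.na(full$geno_missing))) full$geno_missing <- FALSE
  full$geno_missing[is.na(full$geno_missing)] <- FALSE
  for (k in 1:10)
    if (all(is.na(full[[paste0("pc", k)]])))
      full[[paste0("pc", k)]] <- 0
  if (all(is.na(full$platform))) full$platform <- "A"
  structure(list(individuals = full[, schema], geno = NULL, maf = NULL,
                 pgi_weights = NULL, config = NULL, schema_version = "1"),
            class = "cohort")
}

# a deterministic analysis fixture: n children in fam-size-2 clusters with
# generic regressors, used for estimator oracle checks
ols_fixture <- function(n = 60, seed = 99, binary = FALSE) {
  set.seed(seed)
  fam <- rep(sprintf("F%03d", 1:(n / 2)), each = 2)
  d <- data.frame(
    person_id = sprintf("P%03d", 1:n), family_id = fam,
    role = rep(c("twin1", "twin2"), n / 2), zygosity = "DZ",
    geno_missing = FALSE,
    pgi_cog = rnorm(n), pgi_noncog = rnorm(n),
    ses = rep(rbinom(n / 2, 1, 0.4), each = 2),
    platform = rep(sample(c("A", "B"), n / 2, TRUE), each = 2),
    stringsAsFactors = FALSE)
  for (k in 1:10) d[[paste0("pc", k)]] <- rnorm(n)
  fam_eff <- rep(rnorm(n / 2, 0, 0.5), each = 2)
  lat <- 0.3 * d$pgi_cog + 0.15 * d$pgi_noncog + 0.4 * d$ses -
    0.2 * d$pgi_cog * d$ses + fam_eff + rnorm(n, 0, 0.8)
  d$math7 <- pmin(pmax(round(lat + 3.5), 1), 5)
  d$cito_z <- as.numeric(scale(lat))
  d$track <- as.integer(lat + rnorm(n, 0, 0.3) > median(lat))
  co <- manual_cohort(d)
  co
}

sample_from <- function(cohort, design = "between", outcome = "cito_z",
                        seed = 1) {
  build_sample(cohort, design, outcome, seed)
}
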