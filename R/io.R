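# Cohort serialisation: one delimited table (one row per individual, with
# genotype dosages as g1..gL columns) plus a sidecar YAML scenario file.

#' Write a cohort to disk
#'
#' Writes `<path>.tsv` (one row per individual; observed genotype dosages as
#' `g1..gL` columns, missing for ungenotyped persons) and a sidecar
#' `<path>.scenario.yaml` holding the schema version, the scenario
#' configuration and the per-locus allele frequencies and index weights, so
#' a written cohort round-trips.
#'
#' @param cohort a `cohort`.
#' @param path file stem (without extension).
#' @param genotypes write genotype columns (default `TRUE`).
#' @return `path`, invisibly.
#' @export
write_cohort <- function(cohort, path, genotypes = TRUE) {
  ind <- cohort$individuals
  tab <- ind
  if (genotypes && !is.null(cohort$geno)) {
    g <- cohort$geno[ind$person_id, , drop = FALSE]
    g[ind$geno_missing, ] <- NA_integer_
    tab <- cbind(ind, as.data.frame(g))
  }
  data.table::fwrite(tab, paste0(path, ".tsv"), sep = "\t", na = "NA")
  scen <- list(schema_version = cohort$schema_version,
               config = unclass(cohort$config),
               maf = as.numeric(cohort$maf))
  if (!is.null(cohort$pgi_weights))
    scen$pgi_weights <- list(cog = as.numeric(cohort$pgi_weights[, "cog"]),
                             noncog = as.numeric(cohort$pgi_weights[, "noncog"]))
  yaml::write_yaml(scen, paste0(path, ".scenario.yaml"))
  invisible(path)
}

#' Read a cohort written by [write_cohort()], or a user-supplied table
#'
#' A user-supplied table must follow the documented column schema (see
#' [write_cohort()]); genotype columns and the sidecar scenario file are
#' optional — the analysis stages only require the individual-level columns.
#'
#' @param path file stem used in [write_cohort()], or a `.tsv` path.
#' @return a `cohort`.
#' @export
read_cohort <- function(path) {
  stem <- sub("\\.tsv$", "", path)
  f <- paste0(stem, ".tsv")
  if (!file.exists(f)) schema_error(sprintf("cohort file not found: %s", f))
  tab <- as.data.frame(data.table::fread(f, sep = "\t", na.strings = "NA"))
  need <- c("person_id", "family_id", "role", "zygosity", "geno_missing",
            "pgi_cog", "pgi_noncog", "ses")
  missing_cols <- setdiff(need, names(tab))
  if (length(missing_cols))
    schema_error(paste("cohort table lacks required columns:",
                       paste(missing_cols, collapse = ", ")))
  gcols <- grep("^g[0-9]+$", names(tab), value = TRUE)
  geno <- NULL
  if (length(gcols)) {
    geno <- as.matrix(tab[, gcols])
    storage.mode(geno) <- "integer"
    rownames(geno) <- tab$person_id
    tab <- tab[, setdiff(names(tab), gcols)]
  }
  for (cc in setdiff(person_schema(), names(tab))) tab[[cc]] <- NA
  config <- NULL; maf <- NULL; weights <- NULL
  scen_f <- paste0(stem, ".scenario.yaml")
  if (file.exists(scen_f)) {
    scen <- yaml::read_yaml(scen_f)
    if (!identical(as.character(scen$schema_version), SCHEMA_VERSION))
      warning(sprintf("cohort schema version %s read by package schema %s",
                      scen$schema_version, SCHEMA_VERSION))
    if (!is.null(scen$config)) {
      config <- scen$config
      config$zygosity_mix <- unlist(config$zygosity_mix)
      class(config) <- "cohort_config"
    }
    maf <- scen$maf
    if (!is.null(scen$pgi_weights))
      weights <- cbind(cog = scen$pgi_weights$cog,
                       noncog = scen$pgi_weights$noncog)
  }
  new_cohort(tab[, person_schema()], geno, maf, config, weights)
}
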