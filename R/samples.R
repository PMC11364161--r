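# Analytical-sample construction for the three research designs.
#
# All selection rules are family-local: whether and which of a family's
# children enter a design sample depends only on that family's own data and
# its own seeded draw. The cluster bootstrap relies on this property.

new_design_sample <- function(design, outcome, data, log, seed) {
  structure(list(design = design, outcome = outcome, data = data,
                 selection_log = log, seed = seed),
            class = "design_sample")
}

#' @export
print.design_sample <- function(x, ...) {
  cat(sprintf("<design_sample> %s / %s: %d children in %d families\n",
              x$design, x$outcome, nrow(x$data),
              length(unique(x$data$family_id))))
  invisible(x)
}

# children with complete analysis data for one outcome
complete_children <- function(cohort, outcome) {
  ind <- cohort$individuals
  ycol <- outcome_column(outcome)
  ok <- ind$role %in% CHILD_ROLES &
    !is.na(ind$pgi_cog) & !is.na(ind$pgi_noncog) &
    !is.na(ind$ses) & !is.na(ind[[ycol]])
  ind[ok, , drop = FALSE]
}

#' Build the between-family analytical sample
#'
#' Retains every child with non-missing polygenic indices, family SES and
#' the named outcome; in families where both monozygotic co-twins are
#' complete, one is dropped at random (seeded per design and outcome), since
#' an identical pair carries no extra genetic information.
#'
#' @param cohort a `cohort`.
#' @param outcome outcome name (see [outcome_columns()]).
#' @param seed master seed; the draw uses `subseed(seed, "between", outcome)`.
#' @return a `design_sample`.
#' @export
build_between <- function(cohort, outcome, seed = 1L) {
  outcome_column(outcome)   # validates
  comp <- complete_children(cohort, outcome)
  set.seed(subseed(seed, "between", outcome))
  is_mz_twin <- comp$zygosity == "MZ" & comp$role %in% c("twin1", "twin2")
  mz_fams <- names(which(table(comp$family_id[is_mz_twin]) == 2L))
  drop_ids <- character(0)
  log <- data.frame(family_id = character(0), rule = character(0),
                    chosen = character(0), stringsAsFactors = FALSE)
  if (length(mz_fams)) {
    pick_twin1 <- stats::runif(length(mz_fams)) < 0.5
    drop_role <- ifelse(pick_twin1, "twin1", "twin2")
    keep_role <- ifelse(pick_twin1, "twin2", "twin1")
    drop_ids <- paste0(mz_fams, "_", drop_role)
    log <- data.frame(family_id = mz_fams, rule = "mz_random_drop",
                      chosen = paste0(mz_fams, "_", keep_role),
                      stringsAsFactors = FALSE)
  }
  keep <- comp[!comp$person_id %in% drop_ids, , drop = FALSE]
  new_design_sample("between", outcome, keep, log, seed)
}

#' Build the within-family analytical sample
#'
#' Keeps a balanced sample of exactly two complete-data children per family
#' for family fixed-effects estimation, applying in order: (1) a complete
#' dizygotic twin pair; (2) one remaining co-twin compared with a complete
#' full sibling (a random one if several); (3) a complete monozygotic pair
#' -- which carries no within-pair genetic variation -- contributes one
#' randomly selected co-twin paired with a sibling. Families without two
#' usable members are dropped and logged. If a family's twins carry mixed
#' zygosity codes (possible only in user-supplied data), a warning is
#' emitted and rule (3) is applied.
#'
#' @inheritParams build_between
#' @return a `design_sample` with exactly two rows per retained family.
#' @export
build_within <- function(cohort, outcome, seed = 1L) {
  outcome_column(outcome)
  comp <- complete_children(cohort, outcome)
  set.seed(subseed(seed, "within", outcome))
  fams <- unique(comp$family_id)
  keep_rows <- vector("list", length(fams))
  log <- vector("list", length(fams))
  by_fam <- split(seq_len(nrow(comp)), comp$family_id)[fams]
  for (i in seq_along(fams)) {
    rows <- by_fam[[i]]
    fam <- comp[rows, , drop = FALSE]
    twins <- fam[fam$role %in% c("twin1", "twin2"), , drop = FALSE]
    sibs <- fam[fam$role == "sibling", , drop = FALSE]
    zygs <- unique(twins$zygosity)
    if (length(zygs) > 1) {
      warning(sprintf("family %s has mixed twin zygosity; applying the monozygotic rule",
                      fams[i]))
      zygs <- "MZ"
    }
    pick_sib <- function() sibs[sample.int(nrow(sibs), 1L), , drop = FALSE]
    sel <- NULL; rule <- NA_character_
    if (nrow(twins) == 2 && identical(zygs, "DZ")) {
      sel <- twins; rule <- "1_dz_pair"
    } else if (nrow(twins) == 1 && nrow(sibs) >= 1) {
      sel <- rbind(twins, pick_sib()); rule <- "2_twin_plus_sibling"
    } else if (nrow(twins) == 2 && identical(zygs, "MZ") && nrow(sibs) >= 1) {
      sel <- rbind(twins[sample.int(2L, 1L), , drop = FALSE], pick_sib())
      rule <- "3_mz_random_twin_plus_sibling"
    } else if (nrow(twins) == 0 && nrow(sibs) >= 2) {
      sel <- sibs[sample.int(nrow(sibs), 2L), , drop = FALSE]
      rule <- "siblings_only"
    }
    if (is.null(sel)) {
      log[[i]] <- data.frame(family_id = fams[i], rule = "dropped",
                             chosen = NA_character_, stringsAsFactors = FALSE)
    } else {
      keep_rows[[i]] <- sel
      log[[i]] <- data.frame(family_id = fams[i], rule = rule,
                             chosen = paste(sel$person_id, collapse = ","),
                             stringsAsFactors = FALSE)
    }
  }
  keep <- do.call(rbind, keep_rows[!vapply(keep_rows, is.null, TRUE)])
  if (is.null(keep)) keep <- comp[0, , drop = FALSE]
  new_design_sample("within", outcome, keep, do.call(rbind, log), seed)
}

#' Build the trio analytical sample
#'
#' The between-family sample further restricted to children whose father's
#' and mother's polygenic indices are both observed, so that both parents'
#' genotypes can be conditioned on.
#'
#' @inheritParams build_between
#' @return a `design_sample`.
#' @export
build_trio <- function(cohort, outcome, seed = 1L) {
  btw <- build_between(cohort, outcome, seed)
  d <- btw$data
  ok <- !is.na(d$pgi_cog_f) & !is.na(d$pgi_cog_m) &
    !is.na(d$pgi_noncog_f) & !is.na(d$pgi_noncog_m)
  dropped_fams <- unique(d$family_id[!ok])
  log <- btw$selection_log
  if (length(dropped_fams))
    log <- rbind(log, data.frame(family_id = dropped_fams,
                                 rule = "parent_genotype_missing",
                                 chosen = NA_character_,
                                 stringsAsFactors = FALSE))
  new_design_sample("trio", outcome, d[ok, , drop = FALSE], log, seed)
}

#' Build the analytical sample for any design
#'
#' @inheritParams build_between
#' @param design one of `"between"`, `"within"`, `"trio"`.
#' @return a `design_sample`.
#' @export
build_sample <- function(cohort, design, outcome, seed = 1L) {
  switch(match.arg(design, c("between", "within", "trio")),
         between = build_between(cohort, outcome, seed),
         within = build_within(cohort, outcome, seed),
         trio = build_trio(cohort, outcome, seed))
}
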