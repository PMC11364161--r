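# Pipeline: the full 2 polygenic indices x 7 outcomes x 3 designs grid,
# sign/significance tallies, hypothesis verdicts and interaction plots.

#' Run the full interaction grid
#'
#' Generates (or loads) one cohort, then for every cell of the
#' 2 indices x 7 outcomes x 3 designs grid estimates the
#' gene-by-environment interaction — the focal-index-by-SES coefficient of
#' the fully interacted model in the between and trio designs, the
#' SES-stratified fixed-effects slope difference in the within design — and
#' applies Bonferroni and Romano-Wolf corrections per (design, index)
#' seven-outcome family. Stage errors are attached to their cells, never
#' silently dropped.
#'
#' @param x a [cohort_config()], a `cohort`, or a path readable by
#'   [read_cohort()].
#' @param seed master seed for sample selection and the bootstrap.
#' @param bootstrap_B Romano-Wolf bootstrap replications; `0` skips the
#'   Romano-Wolf correction (its columns are `NA`).
#' @param alpha familywise level.
#' @param outcomes outcome names (default all seven).
#' @return object of class `grid_result` with `cells` (one row per cell),
#'   `tally`, per-family `corrections`, stored `fits`, and a scenario hash.
#' @export
run_grid <- function(x, seed = 1L, bootstrap_B = 1000, alpha = 0.05,
                     outcomes = names(outcome_columns())) {
  cohort <- if (inherits(x, "cohort_config")) simulate_cohort(x)
  else if (inherits(x, "cohort")) x
  else if (is.character(x)) read_cohort(x)
  else contract_error("x must be a cohort_config, cohort or file path")
  designs <- c("between", "within", "trio")
  pgis <- c("cog", "noncog")
  cells <- list(); corrections <- list(); fits <- list()
  # one design sample per (design, outcome); shared by both focal indices
  sample_cache <- list()
  get_sample <- function(design, o) {
    key <- paste(design, o, sep = ".")
    if (is.null(sample_cache[[key]]))
      sample_cache[[key]] <<- build_sample(cohort, design, o, seed)
    sample_cache[[key]]
  }
  for (design in designs) for (pgi in pgis) {
    fam_id <- paste(design, pgi, sep = ".")
    focal <- paste0("pgi_", pgi)
    preps <- list(); errs <- setNames(rep(NA_character_, length(outcomes)),
                                      outcomes)
    for (o in outcomes) {
      p <- tryCatch({
        smp <- get_sample(design, o)
        h <- if (design == "within") {
          make_hypothesis(smp, expand_baseline("within", o), focal,
                          "strat_diff")
        } else {
          make_hypothesis(smp, expand_interacted(design, o, pgi),
                          paste0(focal, ":ses"), "coef")
        }
        prep_hypothesis(h)
      }, error = function(e) conditionMessage(e))
      if (is.character(p)) errs[o] <- p else preps[[o]] <- p
    }
    res <- NULL
    if (length(preps)) {
      res <- tryCatch({
        if (bootstrap_B > 0) {
          romano_wolf_core(preps, B = bootstrap_B, seed = seed,
                           alpha = alpha, max_redraw = bootstrap_B)
        } else {
          p_raw <- vapply(preps, function(p) p$p_raw, 0)
          bonf <- bonferroni_adjust(unname(p_raw), alpha)
          tab <- data.frame(
            outcome = names(preps),
            estimate = vapply(preps, function(p) p$est0, 0),
            se = vapply(preps, function(p) p$se0, 0),
            t = vapply(preps, function(p) p$est0 / p$se0, 0),
            n = vapply(preps, function(p) p$n, 0),
            n_clusters = vapply(preps, function(p) p$n_clusters, 0),
            p_raw = unname(p_raw), p_bonf = bonf$p_adj, p_rw = NA_real_,
            sig_raw = unname(p_raw) < alpha, sig_bonf = bonf$sig,
            sig_rw = NA, stringsAsFactors = FALSE)
          structure(list(table = tab, alpha = alpha, B = 0L, seed = seed,
                         n_redraw = 0L, threshold_bonf = bonf$threshold,
                         fits = lapply(preps, `[[`, "fits")),
                    class = "correction_result")
        }
      }, error = function(e) conditionMessage(e))
    }
    if (is.character(res) || is.null(res)) {
      if (is.character(res)) errs[names(preps)] <- res
      res <- NULL
    }
    corrections[[fam_id]] <- res
    fits[[fam_id]] <- if (!is.null(res)) res$fits else NULL
    for (o in outcomes) {
      row <- data.frame(design = design, outcome = o, focal_pgi = pgi,
                        estimate = NA_real_, se = NA_real_,
                        p_raw = NA_real_, p_bonf = NA_real_, p_rw = NA_real_,
                        sig_raw = NA, sig_bonf = NA, sig_rw = NA,
                        n = NA_real_, n_clusters = NA_real_,
                        error = errs[[o]], stringsAsFactors = FALSE)
      if (!is.null(res) && o %in% res$table$outcome) {
        tr <- res$table[res$table$outcome == o, ]
        row[c("estimate", "se", "p_raw", "p_bonf", "p_rw")] <-
          tr[c("estimate", "se", "p_raw", "p_bonf", "p_rw")]
        row[c("sig_raw", "sig_bonf", "sig_rw")] <-
          tr[c("sig_raw", "sig_bonf", "sig_rw")]
        row[c("n", "n_clusters")] <- tr[c("n", "n_clusters")]
      }
      cells[[length(cells) + 1L]] <- row
    }
  }
  cells <- do.call(rbind, cells)
  est <- cells$estimate
  tally <- list(
    n_cells = nrow(cells),
    n_negative = sum(est < 0, na.rm = TRUE),
    n_positive = sum(est > 0, na.rm = TRUE),
    n_zero = sum(est == 0, na.rm = TRUE),
    n_error = sum(!is.na(cells$error)),
    n_sig_raw = sum(cells$sig_raw, na.rm = TRUE),
    n_sig_rw = if (bootstrap_B > 0) sum(cells$sig_rw, na.rm = TRUE) else NA,
    n_sig_bonf = sum(cells$sig_bonf, na.rm = TRUE))
  cfg <- if (inherits(x, "cohort_config")) x else cohort$config
  hash <- fnv1a(paste(c(deparse(unclass(cfg)), seed), collapse = ";"))
  structure(list(cells = cells, tally = tally, corrections = corrections,
                 fits = fits, scenario_hash = hash, seed = seed,
                 alpha = alpha, bootstrap_B = bootstrap_B,
                 config = cfg),
            class = "grid_result")
}

#' @export
print.grid_result <- function(x, ...) {
  t <- x$tally
  cat(sprintf("<grid_result> %d cells (scenario %s, seed %d)\n",
              t$n_cells, x$scenario_hash, x$seed))
  cat(sprintf("  sign: %d negative / %d positive interactions\n",
              t$n_negative, t$n_positive))
  cat(sprintf("  significant at %.2g: %d raw, %s Romano-Wolf, %d Bonferroni\n",
              x$alpha, t$n_sig_raw,
              if (is.na(t$n_sig_rw)) "-" else t$n_sig_rw, t$n_sig_bonf))
  if (t$n_error > 0) cat(sprintf("  %d cells carry errors\n", t$n_error))
  invisible(x)
}

#' Classify the grid against the two competing hypotheses
#'
#' A positive, robust interaction pattern supports the hypothesis that
#' enriched environments let genetic propensity express more strongly
#' (Scarr-Rowe); a negative pattern supports compensation by high-SES
#' families. Counts are split by correction level.
#'
#' @param grid a `grid_result`.
#' @param alpha significance level for the verdict.
#' @return list of class `support_verdict` with per-hypothesis counts and a
#'   verdict string.
#' @export
classify_support <- function(grid, alpha = grid$alpha) {
  cells <- grid$cells
  ok <- !is.na(cells$estimate)
  neg <- ok & cells$estimate < 0
  pos <- ok & cells$estimate > 0
  counts <- list(
    n_cells = sum(ok),
    h1_positive = sum(pos),
    h1_sig_raw = sum(pos & cells$sig_raw, na.rm = TRUE),
    h1_sig_rw = sum(pos & cells$sig_rw, na.rm = TRUE),
    h1_sig_bonf = sum(pos & cells$sig_bonf, na.rm = TRUE),
    h2_negative = sum(neg),
    h2_sig_raw = sum(neg & cells$sig_raw, na.rm = TRUE),
    h2_sig_rw = sum(neg & cells$sig_rw, na.rm = TRUE),
    h2_sig_bonf = sum(neg & cells$sig_bonf, na.rm = TRUE))
  verdict <- if (counts$h1_positive > counts$h2_negative) {
    if (counts$h1_sig_bonf > 0) "H1 (enriched-environment expression), robust to Bonferroni"
    else if (counts$h1_sig_raw > 0) "sign-consistent with H1, partially significant"
    else "sign-consistent with H1, not robust"
  } else if (counts$h2_negative > counts$h1_positive) {
    if (counts$h2_sig_bonf > 0) "H2 (compensatory advantage), robust to Bonferroni"
    else if (counts$h2_sig_raw > 0) "sign-consistent with H2, partially significant"
    else "sign-consistent with H2, not robust"
  } else "no dominant sign pattern (null)"
  structure(c(counts, list(verdict = verdict, alpha = alpha)),
            class = "support_verdict")
}

#' @export
print.support_verdict <- function(x, ...) {
  cat(sprintf("<support_verdict> %s\n", x$verdict))
  cat(sprintf("  positive (H1): %d cells (%d raw / %s RW / %d Bonferroni significant)\n",
              x$h1_positive, x$h1_sig_raw,
              as.character(x$h1_sig_rw), x$h1_sig_bonf))
  cat(sprintf("  negative (H2): %d cells (%d raw / %s RW / %d Bonferroni significant)\n",
              x$h2_negative, x$h2_sig_raw,
              as.character(x$h2_sig_rw), x$h2_sig_bonf))
  invisible(x)
}

# predicted outcome and delta-method band over the focal index for SES 0/1
predict_cell <- function(fit, focal_var, pgi_range = c(-2, 2),
                         npoints = 41, level = 0.95) {
  cols <- names(fit$coef)
  xm <- fit$x_means
  xs <- seq(pgi_range[1], pgi_range[2], length.out = npoints)
  rows <- list()
  for (s in c(0, 1)) {
    NewX <- vapply(cols, function(cn) {
      if (cn == "(Intercept)") return(rep(1, npoints))
      parts <- strsplit(cn, ":", fixed = TRUE)[[1]]
      comp <- lapply(parts, function(pp) {
        if (pp == focal_var) xs
        else if (pp == "ses") rep(s, npoints)
        else rep(unname(xm[pp]), npoints)
      })
      Reduce(`*`, comp)
    }, numeric(npoints))
    NewX <- matrix(NewX, nrow = npoints, dimnames = list(NULL, cols))
    pred <- drop(NewX %*% fit$coef)
    sep <- sqrt(rowSums((NewX %*% fit$vcov) * NewX))
    q <- stats::qt(1 - (1 - level) / 2, fit$df)
    rows[[length(rows) + 1L]] <- data.frame(
      pgi = xs, ses = s, pred = pred, se = sep,
      lo = pred - q * sep, hi = pred + q * sep)
  }
  do.call(rbind, rows)
}

#' Plot predicted outcomes by focal index and family SES
#'
#' For each between- or trio-design cell, plots the predicted outcome over
#' the focal index in `[-2, 2]` for low- and high-SES families, with 95%
#' bands from the family-clustered covariance (delta method), covariates
#' held at sample means. Under a negative interaction the high-SES line is
#' flatter — the compensation pattern. Within-design cells have no
#' level-scale prediction (the family intercepts are absorbed) and are
#' skipped with a log entry.
#'
#' @param grid a `grid_result` from [run_grid()].
#' @param outdir optional directory; plots are saved as one PDF per cell.
#' @param designs designs to plot.
#' @param level confidence level of the bands.
#' @return invisible list with `plots` (named ggplot objects), `data`
#'   (per-cell prediction frames) and `skipped`.
#' @export
plot_interactions <- function(grid, outdir = NULL,
                              designs = c("between", "trio"),
                              level = 0.95) {
  plots <- list(); preds <- list(); skipped <- character(0)
  for (fam_id in names(grid$fits)) {
    parts <- strsplit(fam_id, ".", fixed = TRUE)[[1]]
    design <- parts[1]; pgi <- parts[2]
    if (!design %in% designs) next
    for (o in names(grid$fits[[fam_id]])) {
      cell <- paste(design, pgi, o, sep = ".")
      cf <- grid$fits[[fam_id]][[o]]
      if (design == "within" || is.null(cf$fit)) {
        skipped <- c(skipped, cell)
        message(sprintf("skipping %s: no level-scale fit to plot", cell))
        next
      }
      pd <- predict_cell(cf$fit, paste0("pgi_", pgi), level = level)
      pd$ses_label <- factor(ifelse(pd$ses == 1, "high SES", "low SES"),
                             levels = c("low SES", "high SES"))
      p <- ggplot2::ggplot(pd, ggplot2::aes(x = .data$pgi, y = .data$pred,
                                            colour = .data$ses_label,
                                            fill = .data$ses_label)) +
        ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$lo, ymax = .data$hi),
                             alpha = 0.2, colour = NA) +
        ggplot2::geom_line(linewidth = 0.8) +
        ggplot2::labs(x = sprintf("%s polygenic index (z-score)",
                                  ifelse(pgi == "cog", "cognitive",
                                         "noncognitive")),
                      y = sprintf("predicted %s", o),
                      colour = NULL, fill = NULL,
                      title = sprintf("%s design: %s", design, o)) +
        ggplot2::theme_minimal()
      plots[[cell]] <- p; preds[[cell]] <- pd
      if (!is.null(outdir)) {
        dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
        ggplot2::ggsave(file.path(outdir, paste0(cell, ".pdf")), p,
                        width = 5, height = 4)
      }
    }
  }
  invisible(list(plots = plots, data = preds, skipped = skipped))
}

#' Tidy long table of all grid cells
#'
#' @param grid a `grid_result`.
#' @return data frame with one row per analysis cell.
#' @export
grid_table <- function(grid) grid$cells
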