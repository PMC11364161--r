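# Model specification: ordered term lists for the three designs, the fully
# interacted (Keller-style) expansions, and the tercile robustness coding.

PARENT_PGI_VARS <- c("pgi_cog_f", "pgi_cog_m", "pgi_noncog_f", "pgi_noncog_m")

control_vars <- function() c(paste0("pc", 1:10), "platform")

term_row <- function(vars, kind) {
  list(name = paste(vars, collapse = ":"), vars = vars, kind = kind)
}

new_model_formula <- function(design, outcome, focal_pgi, terms,
                              pgi_coding = "zscore", tercile_cuts = NULL) {
  structure(list(design = design, outcome = outcome, focal_pgi = focal_pgi,
                 terms = terms, pgi_coding = pgi_coding,
                 tercile_cuts = tercile_cuts),
            class = "model_formula")
}

#' @export
print.model_formula <- function(x, ...) {
  cat(sprintf("<model_formula> %s / %s (focal: %s, coding: %s)\n",
              x$design, x$outcome, x$focal_pgi %||% "none", x$pgi_coding))
  cat(formula_text(x), "\n")
  invisible(x)
}

#' Human-readable text form of a model formula
#'
#' @param formula a `model_formula`.
#' @return a single string, e.g. `"math7 ~ pgi_cog + ... + pgi_cog:ses | family FE"`.
#' @export
formula_text <- function(formula) {
  nm <- vapply(formula$terms, `[[`, "", "name")
  fe <- vapply(formula$terms, `[[`, "", "kind") == "fixed-effect-absorbed"
  rhs <- paste(nm[!fe], collapse = " + ")
  txt <- paste(formula$outcome, "~", rhs)
  if (any(fe)) txt <- paste(txt, "| family FE")
  txt
}

#' Baseline (main-effects) model for a design
#'
#' Between-family: the two child polygenic indices, family SES and the 11
#' controls (10 ancestry principal components and the platform indicator).
#' Within-family: the same without SES — any family-constant term is
#' inestimable under family fixed effects, which are marked as an absorbed
#' term. Trio: the between-family terms plus the four parental indices.
#'
#' @param design `"between"`, `"within"` or `"trio"`.
#' @param outcome outcome name.
#' @return a `model_formula`.
#' @export
expand_baseline <- function(design, outcome) {
  design <- match.arg(design, c("between", "within", "trio"))
  outcome_column(outcome)
  terms <- list(term_row("pgi_cog", "main"), term_row("pgi_noncog", "main"))
  if (design != "within") terms <- c(terms, list(term_row("ses", "main")))
  if (design == "trio")
    terms <- c(terms, lapply(PARENT_PGI_VARS, term_row, kind = "main"))
  terms <- c(terms, lapply(control_vars(), term_row, kind = "main"))
  if (design == "within")
    terms <- c(terms, list(term_row("family_fe", "fixed-effect-absorbed")))
  new_model_formula(design, outcome, NULL, terms)
}

#' Fully interacted gene-by-environment model
#'
#' Adds to the baseline, in order: focal index × SES (the coefficient of
#' interest), focal × other index, (trio) focal × each parental index,
#' focal × each control, SES × other index, (trio) SES × each parental
#' index, and SES × each control. Interacting the focal index and the
#' moderator with every covariate is the standard guard against the
#' gene-environment interaction absorbing confounded covariate
#' interactions. Covariate × covariate terms are never generated.
#'
#' @inheritParams expand_baseline
#' @param focal_pgi `"cog"` or `"noncog"`.
#' @return a `model_formula`.
#' @export
expand_interacted <- function(design, outcome, focal_pgi) {
  design <- match.arg(design, c("between", "trio"))
  if (is.null(focal_pgi) || !focal_pgi %in% c("cog", "noncog"))
    contract_error("focal_pgi must be 'cog' or 'noncog' for an interacted model")
  base <- expand_baseline(design, outcome)
  focal <- paste0("pgi_", focal_pgi)
  other <- setdiff(c("pgi_cog", "pgi_noncog"), focal)
  inter <- list(term_row(c(focal, "ses"), "interaction"),
                term_row(c(focal, other), "interaction"))
  if (design == "trio")
    inter <- c(inter, lapply(PARENT_PGI_VARS, function(v)
      term_row(c(focal, v), "interaction")))
  inter <- c(inter, lapply(control_vars(), function(v)
    term_row(c(focal, v), "interaction")))
  inter <- c(inter, list(term_row(c("ses", other), "interaction")))
  if (design == "trio")
    inter <- c(inter, lapply(PARENT_PGI_VARS, function(v)
      term_row(c("ses", v), "interaction")))
  inter <- c(inter, lapply(control_vars(), function(v)
    term_row(c("ses", v), "interaction")))
  new_model_formula(design, outcome, focal_pgi, c(base$terms, inter))
}

#' Recode the focal polygenic index into terciles
#'
#' Replaces each z-scored focal index by two indicator terms (middle and top
#' tercile; bottom tercile is the reference), with boundaries computed on
#' the design sample; every term involving the index — including its whole
#' interaction set — is expanded indicator-wise. Used as a robustness coding
#' against nonlinearity in the index.
#'
#' @param formula a `model_formula` with `pgi_coding = "zscore"`.
#' @param data the design-sample data the boundaries are computed on.
#' @return a `model_formula` with `pgi_coding = "terciles"`.
#' @export
recode_terciles <- function(formula, data) {
  if (formula$pgi_coding != "zscore")
    contract_error("terciles can only be derived from the z-score coding")
  vars <- if (!is.null(formula$focal_pgi))
    paste0("pgi_", formula$focal_pgi) else c("pgi_cog", "pgi_noncog")
  cuts <- list()
  for (v in vars) {
    x <- data[[v]]
    q <- stats::quantile(x, c(1/3, 2/3), type = 1, na.rm = TRUE, names = FALSE)
    if (!all(is.finite(q)) || q[1] >= q[2])
      degenerate_error(sprintf("tercile boundaries undefined for '%s' (ties or constant values)", v))
    cuts[[v]] <- q
  }
  recode_term <- function(tr) {
    hit <- tr$vars %in% vars
    if (!any(hit)) return(list(tr))
    v <- tr$vars[hit][1]
    lapply(c("_t2", "_t3"), function(sfx) {
      nv <- tr$vars; nv[nv == v] <- paste0(v, sfx)
      term_row(nv, tr$kind)
    })
  }
  terms <- do.call(c, lapply(formula$terms, recode_term))
  new_model_formula(formula$design, formula$outcome, formula$focal_pgi,
                    terms, pgi_coding = "terciles", tercile_cuts = cuts)
}

# --- design-matrix construction -------------------------------------------

# expand one variable to its column(s) for the model matrix
var_columns <- function(v, data, cuts = NULL) {
  if (v %in% names(data)) {
    col <- data[[v]]
    if (is.character(col) || is.factor(col)) {
      f <- factor(col)
      lev <- levels(f)
      if (length(lev) < 2)
        return(matrix(numeric(nrow(data)), ncol = 1,
                      dimnames = list(NULL, paste0(v, lev[1]))) * 0)
      m <- sapply(lev[-1], function(l) as.numeric(f == l))
      m <- matrix(m, nrow = nrow(data),
                  dimnames = list(NULL, paste0(v, lev[-1])))
      return(m)
    }
    return(matrix(as.numeric(col), ncol = 1, dimnames = list(NULL, v)))
  }
  # tercile indicator derived from a z-scored index
  if (grepl("_t[23]$", v)) {
    base <- sub("_t[23]$", "", v)
    if (is.null(cuts[[base]]))
      schema_error(sprintf("no tercile cuts recorded for '%s'", base))
    q <- cuts[[base]]
    x <- data[[base]]
    ind <- if (endsWith(v, "_t2")) as.numeric(x > q[1] & x <= q[2])
           else as.numeric(x > q[2])
    return(matrix(ind, ncol = 1, dimnames = list(NULL, v)))
  }
  schema_error(sprintf("variable '%s' not found in the sample", v))
}

#' Build the design matrix realising a model formula
#'
#' Categorical controls expand to indicator columns (reference level
#' dropped); an interaction term involving a categorical variable yields one
#' product column per indicator level. Fixed-effect-absorbed markers produce
#' no columns. No intercept column is included.
#'
#' @param formula a `model_formula`.
#' @param data design-sample data.
#' @return list with `X` (numeric matrix), and `term_map` (named list of the
#'   constituent variables behind every column).
#' @export
build_design_matrix <- function(formula, data) {
  cols <- list(); term_map <- list()
  for (tr in formula$terms) {
    if (tr$kind == "fixed-effect-absorbed") next
    mats <- lapply(tr$vars, var_columns, data = data,
                   cuts = formula$tercile_cuts)
    m <- mats[[1]]
    if (length(mats) > 1) {
      for (k in 2:length(mats)) {
        prod_cols <- list()
        for (a in seq_len(ncol(m))) for (b in seq_len(ncol(mats[[k]]))) {
          pc <- m[, a] * mats[[k]][, b]
          prod_cols[[paste0(colnames(m)[a], ":", colnames(mats[[k]])[b])]] <- pc
        }
        m <- do.call(cbind, prod_cols)
        colnames(m) <- names(prod_cols)
      }
    }
    for (j in seq_len(ncol(m))) {
      nm <- colnames(m)[j]
      cols[[nm]] <- m[, j]
      term_map[[nm]] <- tr$vars
    }
  }
  X <- do.call(cbind, cols)
  if (is.null(X)) X <- matrix(numeric(0), nrow(data), 0)
  colnames(X) <- names(cols)
  list(X = X, term_map = term_map)
}

#' Count the estimated slopes a formula produces on a given sample
#'
#' @param formula a `model_formula`.
#' @param data design-sample data.
#' @return integer number of slope columns (intercept excluded).
#' @export
n_slopes <- function(formula, data) ncol(build_design_matrix(formula, data)$X)
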