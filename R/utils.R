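# Internal helpers: structured errors, deterministic sub-seeding, small utilities.

gxe_stop <- function(class, msg, ...) {
  stop(errorCondition(msg, ..., class = c(class, "gxefam_error")))
}

config_error   <- function(msg, ...) gxe_stop("gxefam_config_error", msg, ...)
schema_error   <- function(msg, ...) gxe_stop("gxefam_schema_error", msg, ...)
contract_error <- function(msg, ...) gxe_stop("gxefam_contract_error", msg, ...)
singular_error <- function(msg, ...) gxe_stop("gxefam_singular_error", msg, ...)
structure_error <- function(msg, ...) gxe_stop("gxefam_structure_error", msg, ...)
degenerate_error <- function(msg, ...) gxe_stop("gxefam_degenerate_error", msg, ...)

#' Derive a named sub-seed from a master seed
#'
#' Every random stage of the package (meiosis, socioeconomic-status
#' assignment, per-design sample selection, bootstrap resampling, ...) draws
#' its own stream from one master seed plus a stage label, so that stages are
#' reproducible independently of each other and random exclusions differ
#' across designs and outcomes. The result is always a non-negative integer
#' below 2^31 - 1.
#'
#' @param seed integer master seed.
#' @param ... character or numeric labels identifying the stage.
#' @return a single integer usable with [set.seed()].
#' @export
subseed <- function(seed, ...) {
  labels <- paste(c(...), collapse = "/")
  h <- as.double(seed %% 2147483647L)
  for (ch in utf8ToInt(labels)) {
    h <- (h * 31 + ch) %% 2147483647
  }
  as.integer(h)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# FNV-1a style hash of a character scalar, returned as hex; used for the
# scenario hash in grid results (no cryptographic intent).
fnv1a <- function(x) {
  stopifnot(is.character(x), length(x) == 1L)
  h <- 2166136261
  for (ch in utf8ToInt(x)) {
    h <- bitwXor(as.integer(h %% 2147483647), ch)
    h <- (as.double(h) * 16777619) %% 2^31
  }
  sprintf("%08x", as.integer(h))
}

is_binary01 <- function(x) {
  u <- unique(x[!is.na(x)])
  length(u) <= 2 && all(u %in% c(0, 1))
}

# Children carry the analysis roles; parents anchor transmission.
CHILD_ROLES  <- c("twin1", "twin2", "sibling")
PARENT_ROLES <- c("father", "mother")

#' Outcome names and their cohort columns
#'
#' The seven educational outcomes: mother-reported grades in mathematics and
#' reading at ages 7 and 10 (1-5 scale), the standardised end-of-primary test
#' score (z-scored), upper-secondary track attendance and adult higher
#' educational attainment (both binary).
#'
#' @return named character vector mapping outcome name to cohort column.
#' @export
outcome_columns <- function() {
  c(math7 = "math7", read7 = "read7", math10 = "math10", read10 = "read10",
    cito = "cito_z", track = "track", attain = "attain")
}

outcome_column <- function(outcome) {
  oc <- outcome_columns()
  if (outcome %in% names(oc)) return(unname(oc[outcome]))
  if (outcome %in% oc) return(outcome)   # column name given directly
  schema_error(sprintf("unknown outcome '%s'; expected one of: %s",
                       outcome, paste(names(oc), collapse = ", ")))
}

binary_outcomes <- function() c("track", "attain")
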