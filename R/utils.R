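# Shared small utilities: seeded evaluation, BH wrapper, reporting helpers.

#' Evaluate an expression under a temporary RNG seed
#'
#' Sets the RNG seed, evaluates `code`, and restores the caller's RNG state,
#' so seeded stages never perturb each other's randomness.
#'
#' @param seed Integer seed.
#' @param code Expression to evaluate.
#' @return The value of `code`.
#' @keywords internal
with_rng_seed <- function(seed, code) {
  stopifnot(is.numeric(seed), length(seed) == 1, is.finite(seed))
  had <- exists(".Random.seed", envir = .GlobalEnv, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = .GlobalEnv) else NULL
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = .GlobalEnv)
    } else if (exists(".Random.seed", envir = .GlobalEnv, inherits = FALSE)) {
      rm(".Random.seed", envir = .GlobalEnv)
    }
  })
  set.seed(as.integer(seed))
  code
}

#' Benjamini-Hochberg adjustment
#'
#' Validated wrapper around the classic step-up false-discovery-rate
#' adjustment: `adj_i = min_{j >= i} m * p_(j) / j`, capped at 1. Used by
#' every multiple-testing stage of the pipeline.
#'
#' @param p Numeric vector of p-values in `[0, 1]`; `NA` is not allowed
#'   (callers exclude flagged/untestable records before adjusting).
#' @return Adjusted p-values in the input order.
#' @export
#' @examples
#' bh_adjust(c(0.01, 0.02, 0.03, 0.5))
bh_adjust <- function(p) {
  if (length(p) == 0) return(numeric(0))
  if (anyNA(p)) stop("bh_adjust: p-values must not contain NA")
  if (!is.numeric(p) || any(p < 0 | p > 1)) {
    stop("bh_adjust: p-values must lie in [0, 1]")
  }
  stats::p.adjust(p, method = "BH")
}

#' Percentage of a count, rounded to one decimal
#'
#' The reporting convention used throughout the pipeline summaries
#' (e.g. significant positive pairs out of pairs tested).
#'
#' @param k Numerator count.
#' @param n Denominator count (> 0).
#' @return `round(100 * k / n, 1)`.
#' @export
#' @examples
#' percent(617, 3834)
percent <- function(k, n) {
  stopifnot(is.numeric(k), is.numeric(n), n > 0)
  round(100 * k / n, 1)
}

# Structured stage logging to stderr; quiet-able for tests.
pipe_log <- function(..., verbose = TRUE) {
  if (isTRUE(verbose)) message("[hepamix] ", ...)
}

# TNM stage as ordinal integer (I..IV -> 1..4).
tnm_to_int <- function(stage) {
  lv <- c("I", "II", "III", "IV")
  out <- match(as.character(stage), lv)
  if (anyNA(out[!is.na(stage)])) {
    bad <- unique(as.character(stage)[is.na(out) & !is.na(stage)])
    stop("unknown TNM stage value(s): ", paste(bad, collapse = ", "))
  }
  out
}
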