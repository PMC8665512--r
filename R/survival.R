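# Recurrence-free survival analyses: early-relapse flags and Fisher
# proportion tests, Kaplan-Meier / log-rank, multivariable Cox (Efron
# ties), and the supervised MI/MA prognostic marker screen.

#' Early-relapse flags
#'
#' Early relapse means the recurrence event occurred within
#' `horizon_months` after surgery. Samples censored before the horizon
#' without an event carry no information about early relapse and are
#' flagged indeterminate (`NA`); they are excluded from proportion tests.
#'
#' @param clinical Validated clinical data.frame.
#' @param horizon_months Horizon (default 24).
#' @return Named integer vector: 1 early relapse, 0 not, `NA`
#'   indeterminate.
#' @export
early_relapse_flag <- function(clinical, horizon_months = 24) {
  validate_clinical(clinical)
  flag <- ifelse(clinical$rfs_event == 1 & clinical$rfs_months <= horizon_months,
                 1L,
                 ifelse(clinical$rfs_months >= horizon_months, 0L, NA_integer_))
  stats::setNames(flag, clinical$sample)
}

#' Pairwise Fisher tests of early-relapse proportions
#'
#' For each requested subgroup pair, a two-sided Fisher's exact test of the
#' 2 x 2 early-relapse table (indeterminate samples excluded). With
#' `strata`, the test is repeated within each stratum (e.g. TNM stage);
#' strata where the table degenerates are skipped.
#'
#' @param flags Result of [early_relapse_flag()].
#' @param labels Named subgroup labels.
#' @param pairs List of length-2 vectors of subgroup labels to compare;
#'   default all pairs.
#' @param strata Optional named stratum labels (same samples).
#' @return data.frame: group1, group2, stratum, n, n_early_1, n_early_2, p
#'   (`NA` with a note in `skipped` when untestable).
#' @export
relapse_proportion_test <- function(flags, labels, pairs = NULL,
                                    strata = NULL) {
  labels <- labels[names(flags)]
  lv <- sort(unique(labels[!is.na(labels)]))
  if (is.null(pairs))
    pairs <- utils::combn(lv, 2, simplify = FALSE)
  strat_lv <- if (is.null(strata)) "all" else sort(unique(stats::na.omit(
    strata[names(flags)])))
  rows <- list(); skipped <- character(0)
  for (st in strat_lv) {
    in_st <- if (is.null(strata)) rep(TRUE, length(flags))
             else !is.na(strata[names(flags)]) & strata[names(flags)] == st
    for (pr in pairs) {
      sel <- in_st & !is.na(flags) & labels %in% pr
      f <- flags[sel]; l <- factor(labels[sel], levels = pr)
      tab <- table(l, factor(f, levels = c(1, 0)))
      if (any(rowSums(tab) == 0)) {
        skipped <- c(skipped, paste0(st, ":", paste(pr, collapse = "-")))
        next
      }
      ft <- stats::fisher.test(tab)
      rows[[length(rows) + 1]] <- data.frame(
        group1 = pr[1], group2 = pr[2], stratum = st, n = sum(sel),
        n_early_1 = tab[1, 1], n_early_2 = tab[2, 1],
        p = ft$p.value, stringsAsFactors = FALSE)
    }
  }
  out <- if (length(rows)) do.call(rbind, c(rows, make.row.names = FALSE))
  else data.frame(group1 = character(0), group2 = character(0),
                  stratum = character(0), n = integer(0),
                  n_early_1 = integer(0), n_early_2 = integer(0),
                  p = numeric(0))
  attr(out, "skipped") <- skipped
  out
}

# Apply administrative censoring at a horizon (never creates events).
admin_censor <- function(time, event, horizon) {
  if (is.null(horizon)) return(list(time = time, event = event))
  over <- time > horizon
  list(time = pmin(time, horizon), event = ifelse(over, 0L, event))
}

#' Kaplan-Meier curves and log-rank test by subgroup
#'
#' Product-limit estimates per group with optional administrative
#' censoring at `horizon_months`, plus the K-group log-rank chi-square
#' (K - 1 degrees of freedom).
#'
#' @param clinical Validated clinical data.frame.
#' @param labels Named subgroup labels.
#' @param horizon_months Optional administrative censoring horizon.
#' @return List: `curves` (data.frame group, time, n_risk, n_event, surv),
#'   `chisq`, `df`, `p`, `n`, `n_events`.
#' @export
km_logrank <- function(clinical, labels, horizon_months = NULL) {
  validate_clinical(clinical)
  idx <- match(names(labels), clinical$sample)
  if (anyNA(idx)) stop("km_logrank: labels name samples absent from clinical")
  ac <- admin_censor(clinical$rfs_months[idx], clinical$rfs_event[idx],
                     horizon_months)
  if (sum(ac$event) == 0)
    stop("km_logrank: no events observed (log-rank undefined)")
  grp <- factor(labels)
  if (nlevels(grp) < 2) stop("km_logrank: need >= 2 groups")
  sv <- survival::Surv(ac$time, ac$event)
  fit <- survival::survfit(sv ~ grp)
  strata_grp <- rep(sub("^grp=", "", names(fit$strata)),
                    times = fit$strata)
  curves <- data.frame(group = strata_grp, time = fit$time,
                       n_risk = fit$n.risk, n_event = fit$n.event,
                       n_censor = fit$n.censor, surv = fit$surv,
                       stringsAsFactors = FALSE)
  sd_ <- survival::survdiff(sv ~ grp)
  df <- nlevels(grp) - 1L
  list(curves = curves, chisq = unname(sd_$chisq), df = df,
       p = stats::pchisq(sd_$chisq, df, lower.tail = FALSE),
       n = length(ac$time), n_events = sum(ac$event))
}

#' Multivariable Cox model of recurrence-free survival
#'
#' Cox partial likelihood with Efron tie handling (months-resolution data
#' guarantees ties). Subgroup labels, if given, enter as factor indicators
#' alongside the clinicopathologic covariates (TNM stage as an ordinal
#' integer). Perfect separation (monotone likelihood) raises an error
#' naming the covariate.
#'
#' @param clinical Validated clinical data.frame.
#' @param labels Optional named subgroup labels.
#' @param covariates Clinical covariate columns (default
#'   `tnm_stage, afp_high, thrombus`).
#' @param horizon_months Optional administrative censoring horizon.
#' @param extra Optional data.frame of additional per-sample covariates
#'   (rownames = sample IDs), e.g. a dichotomized marker.
#' @param ties Tie handling, `"efron"` (default) or `"breslow"`.
#' @return List of class `cox_fit`: `coefficients` (data.frame term, coef,
#'   hr, se, z, p), `loglik`, `score_chisq`, `converged`, `n`, `n_events`.
#' @export
cox_multivariable <- function(clinical, labels = NULL,
                              covariates = c("tnm_stage", "afp_high",
                                             "thrombus"),
                              horizon_months = NULL, extra = NULL,
                              ties = c("efron", "breslow")) {
  ties <- match.arg(ties)
  validate_clinical(clinical)
  dat <- clinical
  if ("tnm_stage" %in% covariates)
    dat$tnm_stage <- tnm_to_int(dat$tnm_stage)
  if (!is.null(labels)) {
    dat <- dat[match(names(labels), dat$sample), , drop = FALSE]
    dat$subgroup <- factor(labels)
  }
  if (!is.null(extra)) {
    dat <- cbind(dat, extra[dat$sample, , drop = FALSE])
    covariates <- c(covariates, colnames(extra))
  }
  ac <- admin_censor(dat$rfs_months, dat$rfs_event, horizon_months)
  dat$.time <- ac$time; dat$.event <- ac$event
  terms <- c(if (!is.null(labels)) "subgroup", covariates)
  keep <- stats::complete.cases(dat[, terms, drop = FALSE])
  dat <- dat[keep, , drop = FALSE]
  fml <- stats::as.formula(paste("survival::Surv(.time, .event) ~",
                                 paste(terms, collapse = " + ")))
  fit <- withCallingHandlers(
    survival::coxph(fml, data = dat, ties = ties),
    warning = function(w) {
      if (grepl("infinite|did not converge|beta may be infinite",
                conditionMessage(w)))
        invokeRestart("muffleWarning")
    })
  co <- stats::coef(fit)
  se <- sqrt(diag(stats::vcov(fit)))
  sep <- abs(co) > 15
  if (any(sep))
    stop("cox_multivariable: monotone likelihood (perfect separation) for: ",
         paste(names(co)[sep], collapse = ", "))
  sm <- summary(fit)
  list(coefficients = data.frame(term = names(co), coef = unname(co),
                                 hr = unname(exp(co)), se = unname(se),
                                 z = unname(co / se),
                                 p = unname(2 * stats::pnorm(-abs(co / se))),
                                 stringsAsFactors = FALSE),
       loglik = fit$loglik[2],
       score_chisq = unname(sm$sctest["test"]),
       converged = fit$iter < 100 && all(is.finite(co)),
       n = fit$n, n_events = fit$nevent)
}

#' Supervised prognostic marker screen
#'
#' Three stages: (1) per protein, a Wilcoxon rank-sum test of MI vs MA
#' phenotype, BH-adjusted; (2) for stage-1 hits, dichotomize at the median
#' (ties assigned to the low group) and test recurrence-free survival by
#' log-rank; (3) multivariable Cox with the clinicopathologic covariates.
#' A marker passes if significant at `alpha` in all three stages. Markers
#' whose median split leaves a group empty are skipped.
#'
#' @param protein [omics_matrix()] with no missing values.
#' @param clinical Validated clinical data.frame with at least 5 MI and
#'   5 MA samples.
#' @param alpha Significance level (default 0.05).
#' @param covariates Cox adjustment covariates.
#' @return data.frame: protein, phenotype_p, phenotype_adj_p, cutoff,
#'   logrank_p, cox_p, passed. Skipped markers listed in the `skipped`
#'   attribute.
#' @export
marker_screen <- function(protein, clinical, alpha = 0.05,
                          covariates = c("tnm_stage", "afp_high",
                                         "thrombus")) {
  validate_clinical(clinical)
  stopifnot(inherits(protein, "omics_matrix"))
  if (anyNA(protein)) stop("marker_screen: impute the protein matrix first")
  samples <- intersect(colnames(protein), clinical$sample)
  cl <- clinical[match(samples, clinical$sample), , drop = FALSE]
  ph <- cl$phenotype
  if (sum(ph == "MI", na.rm = TRUE) < 5 || sum(ph == "MA", na.rm = TRUE) < 5)
    stop("marker_screen: need >= 5 samples per phenotype")
  x <- unclass(protein)[, samples, drop = FALSE]
  mi <- which(!is.na(ph) & ph == "MI")
  ma <- which(!is.na(ph) & ph == "MA")
  p1 <- apply(x, 1, function(v)
    suppressWarnings(stats::wilcox.test(v[mi], v[ma], exact = FALSE))$p.value)
  p1[is.na(p1)] <- 1
  adj1 <- bh_adjust(p1)
  hits <- rownames(x)[adj1 < alpha]
  rows <- list(); skipped <- character(0)
  for (g in hits) {
    v <- x[g, ]
    cutoff <- stats::median(v)
    high <- as.integer(v > cutoff)       # ties to the low group
    if (length(unique(high)) < 2) { skipped <- c(skipped, g); next }
    lr <- try(km_logrank(cl, stats::setNames(
      ifelse(high == 1, "high", "low"), samples)), silent = TRUE)
    if (inherits(lr, "try-error")) { skipped <- c(skipped, g); next }
    cx <- try(cox_multivariable(
      cl, covariates = covariates,
      extra = data.frame(marker_high = high, row.names = samples)),
      silent = TRUE)
    if (inherits(cx, "try-error")) { skipped <- c(skipped, g); next }
    cox_p <- cx$coefficients$p[cx$coefficients$term == "marker_high"]
    rows[[g]] <- data.frame(
      protein = g, phenotype_p = p1[g], phenotype_adj_p = adj1[g],
      cutoff = cutoff, logrank_p = lr$p, cox_p = cox_p,
      passed = adj1[g] < alpha && lr$p < alpha && cox_p < alpha,
      stringsAsFactors = FALSE)
  }
  out <- if (length(rows)) do.call(rbind, c(rows, make.row.names = FALSE))
  else data.frame(protein = character(0), phenotype_p = numeric(0),
                  phenotype_adj_p = numeric(0), cutoff = numeric(0),
                  logrank_p = numeric(0), cox_p = numeric(0),
                  passed = logical(0))
  attr(out, "skipped") <- skipped
  attr(out, "n_stage1_hits") <- length(hits)
  out
}
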