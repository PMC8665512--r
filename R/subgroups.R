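# Proteomic subgroup discovery: consensus k-medoids clustering over
# resampled sample subsets, Kruskal-Wallis differential expression,
# clinical association tests, microenvironment signature scores, and
# cross-omics overlap reporting.

#' Consensus clustering of samples
#'
#' Features are z-scored; sample-sample distance is 1 minus the Spearman
#' correlation. For each candidate K, `n_resamples` k-medoids runs on
#' random sample subsets are aggregated into a consensus matrix
#' (co-clustering frequency among co-sampled pairs). Final labels cut an
#' average-linkage tree of `1 - consensus` at K. Unless `fixed_k` is given,
#' K is chosen by minimizing the proportion of ambiguous clustering (PAC:
#' the fraction of consensus entries in `(0.1, 0.9)`), the stability
#' statistic that directly rewards an all-or-nothing consensus; ties go to
#' the smaller K. The consensus-CDF area and its relative gain are also
#' reported in the selection trace.
#'
#' @param m An [omics_matrix()] with no missing values (features x samples).
#' @param k_range Candidate cluster numbers, within `[2, n_samples - 1]`.
#' @param n_resamples Resampling runs per K (default 1000).
#' @param subsample_fraction Fraction of samples drawn per run (default 0.8).
#' @param seed Integer seed.
#' @param fixed_k Optional fixed K (skips selection).
#' @return List of class `subgroup_assignment`: `labels` (named integer),
#'   `k`, `consensus` (sample x sample, for the selected K),
#'   `selection_trace` (data.frame k/area/delta).
#' @export
consensus_cluster <- function(m, k_range = 2:6, n_resamples = 1000,
                              subsample_fraction = 0.8, seed = 1,
                              fixed_k = NULL) {
  stopifnot(inherits(m, "omics_matrix"))
  if (anyNA(m)) stop("consensus_cluster: matrix must be imputed first")
  n <- ncol(m)
  if (any(k_range < 2 | k_range > n - 1))
    stop("consensus_cluster: k_range must lie in [2, n_samples - 1]")
  if (!is.null(fixed_k) && !(fixed_k %in% k_range))
    k_range <- sort(unique(c(k_range, fixed_k)))
  x <- t(scale(t(unclass(m))))           # z-score features
  x <- x[apply(x, 1, function(r) all(is.finite(r))), , drop = FALSE]
  rho <- stats::cor(x, method = "spearman")
  D <- 1 - rho
  n_sub <- max(2, round(subsample_fraction * n))

  run_k <- function(k) {
    co <- matrix(0, n, n); tog <- matrix(0, n, n)
    for (b in seq_len(n_resamples)) {
      idx <- sort(sample.int(n, n_sub))
      cl <- cluster::pam(stats::as.dist(D[idx, idx]), k = k,
                         cluster.only = TRUE, pamonce = 5)
      same <- outer(cl, cl, "==")
      co[idx, idx] <- co[idx, idx] + same
      tog[idx, idx] <- tog[idx, idx] + 1
    }
    cons <- ifelse(tog > 0, co / pmax(tog, 1), 0)
    diag(cons) <- 1
    cons
  }

  res <- with_rng_seed(seed, lapply(sort(k_range), run_k))
  ks <- sort(k_range)
  # area under the consensus CDF = 1 - mean of off-diagonal entries;
  # PAC = proportion of ambiguous (unstable) co-clustering frequencies
  area <- vapply(res, function(cs) 1 - mean(cs[upper.tri(cs)]), 0)
  pac <- vapply(res, function(cs) {
    v <- cs[upper.tri(cs)]
    mean(v > 0.1 & v < 0.9)
  }, 0)
  delta <- c(area[1], diff(area) / area[-length(area)])
  trace <- data.frame(k = ks, area = area, delta = delta, pac = pac)
  k_sel <- if (!is.null(fixed_k)) fixed_k else ks[which.min(pac)]
  cons <- res[[match(k_sel, ks)]]
  dimnames(cons) <- list(colnames(m), colnames(m))
  hc <- stats::hclust(stats::as.dist(1 - cons), method = "average")
  labels <- stats::cutree(hc, k = k_sel)
  names(labels) <- colnames(m)
  structure(list(labels = labels, k = k_sel, consensus = cons,
                 selection_trace = trace), class = "subgroup_assignment")
}

#' @export
print.subgroup_assignment <- function(x, ...) {
  cat(sprintf("subgroup_assignment: K = %d, sizes %s\n", x$k,
              paste(table(x$labels), collapse = "/")))
  invisible(x)
}

#' Kruskal-Wallis differential expression across groups
#'
#' Per feature, the tie-corrected Kruskal-Wallis statistic with a
#' chi-square p-value on K-1 degrees of freedom, BH-adjusted across
#' features. With two groups the test is equivalent to the tie-corrected
#' Wilcoxon rank-sum chi-square (used for thrombus and single-protein
#' comparisons with no separate code path).
#'
#' @param m An [omics_matrix()] with no missing values.
#' @param labels Named group labels covering the columns of `m`; every
#'   group must have at least 2 samples.
#' @param alpha Significance level on the adjusted p (default 0.05).
#' @return data.frame: feature, H, p, adj_p, significant, plus one
#'   `median_<group>` column per group.
#' @export
kw_differential <- function(m, labels, alpha = 0.05) {
  stopifnot(inherits(m, "omics_matrix"))
  if (anyNA(m)) stop("kw_differential: matrix must have no missing values")
  labels <- labels[colnames(m)]
  if (anyNA(labels)) stop("kw_differential: labels missing for some samples")
  g <- factor(labels)
  if (nlevels(g) < 2) stop("kw_differential: need >= 2 groups")
  if (any(table(g) < 2)) stop("kw_differential: every group needs >= 2 samples")
  x <- unclass(m)
  stat <- apply(x, 1, function(v) {
    kt <- stats::kruskal.test(v, g)
    c(kt$statistic, kt$p.value)
  })
  med <- t(apply(x, 1, function(v) tapply(v, g, stats::median)))
  colnames(med) <- paste0("median_", levels(g))
  out <- data.frame(feature = rownames(x), H = stat[1, ], p = stat[2, ],
                    stringsAsFactors = FALSE, row.names = NULL)
  # constant features give H = 0 and NaN p (no variation); treat as p = 1
  out$p[is.nan(out$p) | is.na(out$p)] <- 1
  out$H[is.nan(out$H)] <- 0
  out$adj_p <- bh_adjust(out$p)
  out$significant <- out$adj_p < alpha
  cbind(out, as.data.frame(med, row.names = NULL))
}

#' Association of subgroups with categorical clinical variables
#'
#' Builds the subgroup x category contingency table per variable and tests
#' independence with Fisher's exact test (exact R x C when the total count
#' is <= 500, otherwise a chi-square fallback, flagged in the `method`
#' column). Missing values and empty categories are dropped.
#'
#' @param labels Named subgroup labels.
#' @param clinical Validated clinical data.frame.
#' @param variables Clinical columns to test.
#' @return data.frame: variable, method, p; contingency tables in the
#'   `tables` attribute.
#' @export
clinical_association <- function(labels, clinical,
                                 variables = c("tnm_stage", "afp_high",
                                               "thrombus", "phenotype")) {
  validate_clinical(clinical)
  rows <- list(); tabs <- list()
  for (v in variables) {
    x <- clinical[[v]][match(names(labels), clinical$sample)]
    ok <- !is.na(x)
    if (!any(ok)) next
    tab <- table(subgroup = labels[ok], category = droplevels(factor(x[ok])))
    tab <- tab[rowSums(tab) > 0, colSums(tab) > 0, drop = FALSE]
    if (ncol(tab) < 2 || nrow(tab) < 2) {
      rows[[v]] <- data.frame(variable = v, method = "skipped (single level)",
                              p = NA_real_, stringsAsFactors = FALSE)
      next
    }
    if (sum(tab) <= 500) {
      ft <- stats::fisher.test(tab, workspace = 2e7)
      rows[[v]] <- data.frame(variable = v, method = "fisher.exact",
                              p = ft$p.value, stringsAsFactors = FALSE)
    } else {
      ct <- suppressWarnings(stats::chisq.test(tab))
      rows[[v]] <- data.frame(variable = v, method = "chisq.fallback",
                              p = ct$p.value, stringsAsFactors = FALSE)
    }
    tabs[[v]] <- tab
  }
  out <- do.call(rbind, c(rows, make.row.names = FALSE))
  attr(out, "tables") <- tabs
  out
}

#' Microenvironment signature scores
#'
#' Per cell type, the mean z-score (across samples, per gene) of the
#' signature's measured genes in each sample. The immune score sums the
#' cell types whose signature description contains "immune", the stroma
#' score those tagged "stromal", and the microenvironment score is their
#' sum (a simplified enrichment-style aggregate; no spillover
#' compensation).
#'
#' @param mrna An [omics_matrix()] of expression (no missing values).
#' @param signatures A [pathway_db()] with `"immune"`/`"stromal"` tags in
#'   the description field.
#' @return data.frame: sample, one column per cell type, `immune_score`,
#'   `stroma_score`, `microenvironment_score`. Signatures with no measured
#'   genes are skipped (listed in the `skipped` attribute).
#' @export
signature_scores <- function(mrna, signatures) {
  stopifnot(inherits(mrna, "omics_matrix"), inherits(signatures, "pathway_db"))
  x <- unclass(mrna)
  sdv <- apply(x, 1, stats::sd)
  z <- (x - rowMeans(x)) / ifelse(sdv == 0, 1, sdv)
  scores <- list(); skipped <- character(0)
  for (nm in names(signatures$genes)) {
    g <- intersect(signatures$genes[[nm]], rownames(z))
    if (length(g) == 0) { skipped <- c(skipped, nm); next }
    scores[[nm]] <- colMeans(z[g, , drop = FALSE])
  }
  if (length(scores) == 0) stop("signature_scores: no signature has measured genes")
  sc <- as.data.frame(scores, check.names = FALSE)
  tag <- tolower(signatures$description[names(scores)])
  imm <- grepl("immune", tag); str <- grepl("stromal", tag)
  out <- data.frame(sample = colnames(x), sc, check.names = FALSE,
                    row.names = NULL)
  out$immune_score <- if (any(imm)) rowSums(sc[, imm, drop = FALSE]) else 0
  out$stroma_score <- if (any(str)) rowSums(sc[, str, drop = FALSE]) else 0
  out$microenvironment_score <- out$immune_score + out$stroma_score
  attr(out, "skipped") <- skipped
  out
}

#' Venn partition sizes of named feature sets
#'
#' Exact counts for every non-empty combination of the sets: the exclusive
#' region size (elements in exactly those sets) and the plain intersection
#' size.
#'
#' @param sets Named list of character vectors.
#' @return data.frame: combination (set names joined by `+`), n_exclusive,
#'   n_intersection.
#' @export
overlap_summary <- function(sets) {
  stopifnot(is.list(sets), !is.null(names(sets)), length(sets) >= 1)
  k <- length(sets)
  universe <- unique(unlist(sets))
  member <- vapply(sets, function(s) universe %in% s,
                   logical(length(universe)))
  if (length(universe) == 1) member <- matrix(member, nrow = 1,
                                              dimnames = list(NULL, names(sets)))
  combos <- expand.grid(rep(list(c(FALSE, TRUE)), k))[-1, , drop = FALSE]
  names(combos) <- names(sets)
  rows <- lapply(seq_len(nrow(combos)), function(i) {
    inc <- unlist(combos[i, ])
    excl <- if (length(universe))
      sum(apply(member, 1, function(r) all(r == inc))) else 0L
    inter <- if (length(universe))
      sum(apply(member[, inc, drop = FALSE], 1, all)) else 0L
    data.frame(combination = paste(names(sets)[inc], collapse = "+"),
               n_exclusive = excl, n_intersection = inter,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, c(rows, make.row.names = FALSE))
}
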