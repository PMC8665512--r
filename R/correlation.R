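# Per-gene mRNA-protein correlation with BH control, and two-sample
# Kolmogorov-Smirnov pathway enrichment over the correlation-ranked genes.

#' Pair protein and mRNA matrices on shared genes and samples
#'
#' Gene/protein identity is a single shared symbol namespace; pairing is by
#' exact symbol match. Both matrices are reduced to the (sorted)
#' intersection of their feature and sample sets.
#'
#' @param protein,mrna [omics_matrix()] objects.
#' @return List with `genes`, `samples`, aligned `protein` and `mrna`
#'   matrices, and the pair/sample counts.
#' @export
pair_genes <- function(protein, mrna) {
  stopifnot(inherits(protein, "omics_matrix"), inherits(mrna, "omics_matrix"))
  genes <- sort(intersect(rownames(protein), rownames(mrna)))
  if (length(genes) == 0) stop("pair_genes: no shared gene symbols")
  samples <- sort(intersect(colnames(protein), colnames(mrna)))
  if (length(samples) == 0) stop("pair_genes: no shared samples")
  list(genes = genes, samples = samples,
       protein = protein[genes, samples],
       mrna = mrna[genes, samples],
       n_pairs = length(genes), n_samples = length(samples))
}

#' Per-gene mRNA-protein correlation
#'
#' Computes, per paired gene, the correlation of transcript and protein
#' abundance across samples (Spearman by default), with two-sided p-values
#' and BH adjustment across all testable genes. "Significant positive"
#' means `adj_p < alpha` and `rho > 0`. Genes with a constant vector (or
#' fewer than 3 complete pairs) are flagged and excluded from the BH
#' denominator.
#'
#' @param paired Result of [pair_genes()].
#' @param method `"spearman"` (default) or `"pearson"`.
#' @param alpha Significance level for the summary (default 0.01).
#' @return List with `records` (data.frame: gene, n_pairs, rho, p, adj_p,
#'   flagged) and `summary` (n_tested, median_rho, n_sig_pos, pct_sig_pos,
#'   n_sig_neg).
#' @export
correlate_expression <- function(paired, method = c("spearman", "pearson"),
                                 alpha = 0.01) {
  method <- match.arg(method)
  pr <- unclass(paired$protein)
  mr <- unclass(paired$mrna)
  res <- lapply(seq_along(paired$genes), function(i) {
    x <- mr[i, ]; y <- pr[i, ]
    ok <- !is.na(x) & !is.na(y)
    n <- sum(ok)
    if (n < 3 || stats::sd(x[ok]) == 0 || stats::sd(y[ok]) == 0) {
      return(list(n = n, rho = NA_real_, p = NA_real_, flagged = TRUE))
    }
    ct <- suppressWarnings(stats::cor.test(x[ok], y[ok], method = method,
                                           exact = FALSE))
    list(n = n, rho = unname(ct$estimate), p = ct$p.value, flagged = FALSE)
  })
  records <- data.frame(
    gene = paired$genes,
    n_pairs = vapply(res, `[[`, 0, "n"),
    rho = vapply(res, `[[`, 0, "rho"),
    p = vapply(res, `[[`, 0, "p"),
    adj_p = NA_real_,
    flagged = vapply(res, `[[`, TRUE, "flagged"),
    stringsAsFactors = FALSE)
  testable <- !records$flagged
  records$adj_p[testable] <- bh_adjust(records$p[testable])
  sig_pos <- testable & records$adj_p < alpha & records$rho > 0
  sig_neg <- testable & records$adj_p < alpha & records$rho < 0
  list(records = records,
       summary = list(n_tested = sum(testable),
                      median_rho = stats::median(records$rho[testable]),
                      n_sig_pos = sum(sig_pos),
                      pct_sig_pos = percent(sum(sig_pos), sum(testable)),
                      n_sig_neg = sum(sig_neg),
                      alpha = alpha))
}

#' Kolmogorov-Smirnov pathway enrichment over gene scores
#'
#' For each pathway with at least `min_members` scored genes (and a
#' non-empty complement), runs a two-sample KS test of member vs non-member
#' scores. Direction is the sign of the member-minus-non-member mean.
#' BH adjustment across the tested pathways.
#'
#' @param scores Named numeric vector of finite per-gene scores (e.g.
#'   mRNA-protein correlations).
#' @param pathways A [pathway_db()].
#' @param min_members Minimum scored members; default 5.
#' @return data.frame: pathway, n_members, mean_score, ks_stat, direction,
#'   p, adj_p. Pathways skipped (too few members or no complement) are
#'   reported in the `skipped` attribute.
#' @export
ks_pathway_enrichment <- function(scores, pathways, min_members = 5) {
  stopifnot(inherits(pathways, "pathway_db"))
  scores <- scores[is.finite(scores)]
  if (is.null(names(scores))) stop("ks_pathway_enrichment: scores must be named")
  rows <- list(); skipped <- character(0)
  for (nm in names(pathways$genes)) {
    member <- intersect(pathways$genes[[nm]], names(scores))
    nonmember <- setdiff(names(scores), member)
    if (length(member) < min_members || length(nonmember) == 0) {
      skipped <- c(skipped, nm)
      next
    }
    ks <- suppressWarnings(stats::ks.test(scores[member], scores[nonmember]))
    rows[[nm]] <- data.frame(
      pathway = nm, n_members = length(member),
      mean_score = mean(scores[member]),
      ks_stat = unname(ks$statistic),
      direction = sign(mean(scores[member]) - mean(scores[nonmember])),
      p = ks$p.value, stringsAsFactors = FALSE)
  }
  out <- if (length(rows)) do.call(rbind, c(rows, make.row.names = FALSE))
  else data.frame(pathway = character(0), n_members = integer(0),
                  mean_score = numeric(0), ks_stat = numeric(0),
                  direction = numeric(0), p = numeric(0))
  out$adj_p <- if (nrow(out)) bh_adjust(out$p) else numeric(0)
  attr(out, "skipped") <- skipped
  out
}
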