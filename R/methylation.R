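# Methylation stage: DMR calling across subgroups on M-values, genomic
# annotation of regions (promoter / gene body / intergenic), the
# two-component Gaussian mixture classifying methylation-attenuated
# proteins, and hypergeometric over-representation of the attenuated set.

#' Call differentially methylated regions across subgroups
#'
#' Regions on sex chromosomes are dropped (autosomes only, logged). Betas
#' are clipped to `[0.001, 0.999]` and transformed to M-values
#' (`log2(beta / (1 - beta))`); per region a Kruskal-Wallis test across
#' subgroups is BH-adjusted across regions. A region is a DMR iff
#' `adj_p < alpha` and the largest pairwise absolute difference of
#' subgroup mean betas is at least `min_delta`.
#'
#' @param meth Beta-domain [omics_matrix()] (regions x samples).
#' @param regions Region table (`chrom, start, end, region_id, linked_gene`).
#' @param labels Named subgroup labels for the samples.
#' @param alpha Adjusted-p threshold (default 0.05).
#' @param min_delta Minimum absolute beta difference (default 0.1).
#' @param verbose Log dropped-region counts.
#' @return data.frame: region_id, chrom, start, end, H, p, adj_p,
#'   max_delta_beta (signed, from the extreme subgroup pair), dmr (logical).
#' @export
call_dmrs <- function(meth, regions, labels, alpha = 0.05, min_delta = 0.1,
                      verbose = TRUE) {
  stopifnot(inherits(meth, "omics_matrix"))
  if (attr(meth, "value_domain") != "beta")
    stop("call_dmrs: methylation matrix must be in the beta domain")
  autosomes <- paste0("chr", 1:22)
  drop_n <- sum(!regions$chrom %in% autosomes)
  if (drop_n > 0)
    pipe_log("call_dmrs: dropping ", drop_n, " non-autosomal region(s)",
             verbose = verbose)
  regions <- regions[regions$chrom %in% autosomes, , drop = FALSE]
  ids <- intersect(regions$region_id, rownames(meth))
  if (length(ids) == 0) stop("call_dmrs: no autosomal region measured")
  regions <- regions[match(ids, regions$region_id), , drop = FALSE]
  b <- unclass(meth)[ids, , drop = FALSE]
  labels <- labels[colnames(b)]
  if (anyNA(labels)) stop("call_dmrs: labels missing for some samples")
  g <- factor(labels)
  bc <- pmin(pmax(b, 0.001), 0.999)
  mval <- log2(bc / (1 - bc))
  kw <- apply(mval, 1, function(v) {
    kt <- stats::kruskal.test(v, g)
    c(H = unname(kt$statistic), p = kt$p.value)
  })
  H <- kw["H", ]; p <- kw["p", ]
  H[is.nan(H)] <- 0; p[is.nan(p) | is.na(p)] <- 1
  gm <- t(apply(b, 1, function(v) tapply(v, g, mean)))
  delta <- apply(gm, 1, function(mm) {
    d <- outer(mm, mm, "-")
    d[which.max(abs(d))]
  })
  out <- data.frame(region_id = ids, chrom = regions$chrom,
                    start = regions$start, end = regions$end,
                    H = H, p = p, adj_p = bh_adjust(p),
                    max_delta_beta = delta, stringsAsFactors = FALSE,
                    row.names = NULL)
  out$dmr <- out$adj_p < alpha & abs(out$max_delta_beta) >= min_delta
  out
}

#' Annotate regions against a gene model
#'
#' Coordinates are 0-based half-open; overlap means any shared base. A
#' region is a `promoter` if it overlaps `[TSS - window, TSS + window)`
#' of any gene (strand-aware TSS), else `gene_body` if it overlaps
#' `[gene_start, gene_end)`, else `intergenic`. Promoter takes precedence;
#' overlap with multiple genes is resolved by the nearest TSS.
#'
#' @param regions Region table.
#' @param gene_model Gene model table (`gene, chrom, tss, strand,
#'   gene_start, gene_end`).
#' @param promoter_window Half-width in bp (default 1500).
#' @return `regions` with `annotation` and `linked_gene` columns replaced
#'   by the computed assignment.
#' @export
annotate_regions <- function(regions, gene_model, promoter_window = 1500) {
  if (any(regions$start < 0 | regions$start >= regions$end))
    stop("annotate_regions: malformed region coordinates")
  ann <- rep("intergenic", nrow(regions))
  gene <- rep(NA_character_, nrow(regions))
  mid <- (regions$start + regions$end) / 2
  for (chr in unique(regions$chrom)) {
    ri <- which(regions$chrom == chr)
    gi <- which(gene_model$chrom == chr)
    if (length(gi) == 0) next
    rs <- regions$start[ri]; re <- regions$end[ri]
    tss <- gene_model$tss[gi]
    ps <- tss - promoter_window; pe <- tss + promoter_window
    gs <- gene_model$gene_start[gi]; ge <- gene_model$gene_end[gi]
    # half-open interval overlap: a.start < b.end && b.start < a.end
    ov_prom <- outer(rs, pe, "<") & outer(re, ps, ">")
    ov_body <- outer(rs, ge, "<") & outer(re, gs, ">")
    dist_tss <- abs(outer(mid[ri], tss, "-"))
    pick <- function(ov) {
      d <- dist_tss
      d[!ov] <- Inf
      hit <- rowSums(ov) > 0
      idx <- apply(d, 1, which.min)
      list(hit = hit, gene = gene_model$gene[gi][idx])
    }
    pr <- pick(ov_prom)
    bd <- pick(ov_body)
    ann[ri[pr$hit]] <- "promoter"
    gene[ri[pr$hit]] <- pr$gene[pr$hit]
    rest <- !pr$hit & bd$hit
    ann[ri[rest]] <- "gene_body"
    gene[ri[rest]] <- bd$gene[rest]
  }
  regions$annotation <- ann
  regions$linked_gene <- gene
  regions
}

#' Two-component Gaussian mixture by EM
#'
#' Univariate EM with deterministic initialization at the means of the
#' lowest and highest quartiles, equal weights, and the pooled SD;
#' converges on the log-likelihood (`tol`, default 1e-8, max 1000
#' iterations). The log-likelihood is checked to be non-decreasing at
#' every iteration. Degenerate fits (component weight < 0.01 or SD <
#' 1e-6, or constant input) fall back to a single component with the
#' `degenerate` flag set.
#'
#' @param x Numeric vector (length >= 2).
#' @param tol Log-likelihood convergence tolerance.
#' @param max_iter Maximum EM iterations.
#' @param init_means Optional length-2 initial means (overrides the
#'   quartile initialization; used to check label invariance).
#' @return List: `means`, `sds`, `weights` (component order: ascending
#'   initial mean unless overridden), `posterior` (matrix n x 2),
#'   `loglik_trace`, `converged`, `degenerate`.
#' @export
fit_gmm2 <- function(x, tol = 1e-8, max_iter = 1000, init_means = NULL) {
  stopifnot(is.numeric(x), length(x) >= 2, all(is.finite(x)))
  n <- length(x)
  degenerate_fit <- function() {
    list(means = c(mean(x), mean(x)),
         sds = c(stats::sd(x), stats::sd(x)),
         weights = c(1, 0),
         posterior = cbind(rep(1, n), rep(0, n)),
         loglik_trace = numeric(0), converged = TRUE, degenerate = TRUE)
  }
  if (stats::sd(x) < 1e-12) return(degenerate_fit())
  if (is.null(init_means)) {
    q <- stats::quantile(x, c(0.25, 0.75))
    init_means <- c(mean(x[x <= q[1]]), mean(x[x >= q[2]]))
  }
  mu <- as.numeric(init_means)
  s <- rep(stats::sd(x), 2)
  w <- c(0.5, 0.5)
  ll_trace <- numeric(0)
  ll_old <- -Inf
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    d <- cbind(w[1] * stats::dnorm(x, mu[1], s[1]),
               w[2] * stats::dnorm(x, mu[2], s[2]))
    tot <- pmax(rowSums(d), 1e-300)
    ll <- sum(log(tot))
    if (is.finite(ll_old) && ll < ll_old - 1e-6 * (1 + abs(ll_old)))
      stop("fit_gmm2: log-likelihood decreased (EM invariant violated)")
    ll_trace <- c(ll_trace, ll)
    r <- d[, 2] / tot
    if (is.finite(ll_old) && abs(ll - ll_old) < tol) { converged <- TRUE; break }
    ll_old <- ll
    n2 <- sum(r); n1 <- n - n2
    if (min(n1, n2) < 1e-10) return(degenerate_fit())
    w <- c(n1, n2) / n
    mu <- c(sum((1 - r) * x) / n1, sum(r * x) / n2)
    s <- sqrt(pmax(c(sum((1 - r) * (x - mu[1])^2) / n1,
                     sum(r * (x - mu[2])^2) / n2), 0))
    if (any(s < 1e-6)) return(degenerate_fit())
  }
  if (any(w < 0.01) || any(s < 1e-6)) return(degenerate_fit())
  post <- {
    d <- cbind(w[1] * stats::dnorm(x, mu[1], s[1]),
               w[2] * stats::dnorm(x, mu[2], s[2]))
    d / pmax(rowSums(d), 1e-300)
  }
  list(means = mu, sds = s, weights = w, posterior = post,
       loglik_trace = ll_trace, converged = converged, degenerate = FALSE)
}

#' Classify methylation-attenuated proteins with a Gaussian mixture
#'
#' Per gene with at least one linked region, the methylation summary is
#' the mean beta over its linked regions; `r_meth_rna` and `r_meth_prot`
#' are Spearman correlations of that summary with mRNA and protein across
#' samples. The attenuation score is `r_meth_prot - r_meth_rna`: positive
#' when methylation's (negative) effect reaches mRNA but is damped at the
#' protein. A two-component Gaussian mixture ([fit_gmm2()]) over all
#' scores separates background from attenuated genes; the attenuated
#' component is the one with the larger mean, and a gene is attenuated iff
#' its posterior for that component is at least `posterior_cutoff`.
#'
#' @param meth Beta-domain [omics_matrix()] (regions x samples).
#' @param mrna,protein Log-abundance [omics_matrix()] objects (no missing
#'   values in `protein`; impute first).
#' @param links data.frame with `region_id` and `linked_gene` columns
#'   (e.g. promoter/gene-body annotated DMRs).
#' @param posterior_cutoff Posterior threshold (default 0.5, maximum a
#'   posteriori).
#' @param seed Kept for interface stability; the fit is deterministic.
#' @return List: `records` (data.frame gene, n_regions, r_meth_rna,
#'   r_meth_prot, atten_score, posterior_attenuated, attenuated), `fit`
#'   (the mixture fit), `summary` (n_analyzed, n_attenuated, pct_attenuated).
#' @export
attenuation_gmm <- function(meth, mrna, protein, links,
                            posterior_cutoff = 0.5, seed = 1) {
  stopifnot(inherits(meth, "omics_matrix"), inherits(mrna, "omics_matrix"),
            inherits(protein, "omics_matrix"))
  links <- links[!is.na(links$linked_gene) &
                   links$region_id %in% rownames(meth), , drop = FALSE]
  genes <- sort(intersect(intersect(unique(links$linked_gene),
                                    rownames(mrna)), rownames(protein)))
  if (length(genes) < 20)
    stop("attenuation_gmm: < 20 analyzable genes (mixture unidentifiable)")
  samples <- Reduce(intersect, list(colnames(meth), colnames(mrna),
                                    colnames(protein)))
  if (length(samples) < 5) stop("attenuation_gmm: < 5 shared samples")
  b <- unclass(meth)[, samples, drop = FALSE]
  mr <- unclass(mrna)[, samples, drop = FALSE]
  pr <- unclass(protein)[, samples, drop = FALSE]
  reg_by_gene <- split(links$region_id, links$linked_gene)
  rec <- lapply(genes, function(g) {
    ms <- colMeans(b[reg_by_gene[[g]], , drop = FALSE])
    r_rna <- suppressWarnings(stats::cor(ms, mr[g, ], method = "spearman",
                                         use = "pairwise.complete.obs"))
    r_prot <- suppressWarnings(stats::cor(ms, pr[g, ], method = "spearman",
                                          use = "pairwise.complete.obs"))
    c(n = length(reg_by_gene[[g]]), r_rna = r_rna, r_prot = r_prot)
  })
  rec <- do.call(rbind, rec)
  records <- data.frame(gene = genes, n_regions = rec[, "n"],
                        r_meth_rna = rec[, "r_rna"],
                        r_meth_prot = rec[, "r_prot"],
                        stringsAsFactors = FALSE, row.names = NULL)
  records <- records[is.finite(records$r_meth_rna) &
                       is.finite(records$r_meth_prot), , drop = FALSE]
  if (nrow(records) < 20)
    stop("attenuation_gmm: < 20 genes with defined correlations")
  records$atten_score <- records$r_meth_prot - records$r_meth_rna
  fit <- fit_gmm2(records$atten_score)
  if (fit$degenerate) {
    records$posterior_attenuated <- 0
    records$attenuated <- FALSE
  } else {
    att_comp <- which.max(fit$means)
    records$posterior_attenuated <- fit$posterior[, att_comp]
    records$attenuated <- records$posterior_attenuated >= posterior_cutoff
  }
  list(records = records, fit = fit,
       summary = list(n_analyzed = nrow(records),
                      n_attenuated = sum(records$attenuated),
                      pct_attenuated = percent(sum(records$attenuated),
                                               nrow(records)),
                      degenerate = fit$degenerate))
}

#' Over-representation of a hit set in pathways
#'
#' One-sided hypergeometric test per pathway of the hit set against the
#' analyzed-gene universe, BH-adjusted.
#'
#' @param hits Character vector, subset of `universe`.
#' @param universe Character vector of analyzed genes.
#' @param pathways A [pathway_db()].
#' @return data.frame: pathway, n_pathway (in universe), n_hits, expected,
#'   p, adj_p.
#' @export
hypergeom_ora <- function(hits, universe, pathways) {
  stopifnot(inherits(pathways, "pathway_db"))
  universe <- unique(universe)
  hits <- unique(hits)
  if (!all(hits %in% universe))
    stop("hypergeom_ora: hits must be a subset of the universe")
  N <- length(universe); n <- length(hits)
  rows <- lapply(names(pathways$genes), function(nm) {
    K <- length(intersect(pathways$genes[[nm]], universe))
    if (K == 0) return(NULL)
    k <- length(intersect(pathways$genes[[nm]], hits))
    p <- stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
    data.frame(pathway = nm, n_pathway = K, n_hits = k,
               expected = n * K / N, p = p, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, c(rows[!vapply(rows, is.null, TRUE)],
                          make.row.names = FALSE))
  if (is.null(out)) stop("hypergeom_ora: no pathway overlaps the universe")
  out$adj_p <- bh_adjust(out$p)
  out
}
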