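# Shared fixtures: a small synthetic cohort spec for fast tests, and
# independent oracles used against the package implementations.

small_spec <- function(...) {
  args <- utils::modifyList(
    list(n_samples = 60, n_genes = 300, n_regions = 450,
         n_pathways = 12, seed = 42), list(...))
  do.call(cohort_spec, args)
}

# tiny omics matrix builder
om <- function(values, domain = "log-abundance",
               features = sprintf("F%02d", seq_len(nrow(values))),
               samples = sprintf("S%02d", seq_len(ncol(values)))) {
  dimnames(values) <- list(features, samples)
  omics_matrix(values, domain)
}

# independent step-up BH oracle (from the definition, not p.adjust)
bh_oracle <- function(p) {
  m <- length(p)
  o <- order(p)
  ranked <- p[o]
  adj <- rev(cummin(rev(m * ranked / seq_len(m))))
  adj <- pmin(adj, 1)
  out <- numeric(m)
  out[o] <- adj
  out
}

# independent two-sided Fisher oracle: enumerate all 2x2 tables with the
# observed margins, sum hypergeometric probabilities <= observed
fisher_oracle <- function(tab) {
  r1 <- sum(tab[1, ]); c1 <- sum(tab[, 1]); n <- sum(tab)
  lo <- max(0, r1 + c1 - n); hi <- min(r1, c1)
  probs <- stats::dhyper(lo:hi, c1, n - c1, r1)
  obs <- stats::dhyper(tab[1, 1], c1, n - c1, r1)
  sum(probs[probs <= obs * (1 + 1e-7)])
}

# adjusted Rand index (mclust's implementation as independent oracle)
ari <- function(a, b) mclust::adjustedRandIndex(a, b)
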