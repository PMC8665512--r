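#!/usr/bin/env Rscript
# Step 2 — mRNA-protein correlation screen with KS pathway enrichment.
#
# Filters proteins missing in > 50% of samples, imputes the remainder,
# pairs genes with the transcriptome, computes per-gene Spearman
# correlations with BH control, and ranks pathways by a two-sample KS test
# of member vs non-member correlations.

library(hepamix)

dir <- "results/cohort"
protein <- read_matrix(file.path(dir, "protein.tsv"))
mrna <- read_matrix(file.path(dir, "mrna.tsv"))
pathways <- read_gmt(file.path(dir, "pathways.gmt"))

filtered <- filter_missing(protein, 0.5)
imputed <- impute_missing(filtered, "half_min")
cat(sprintf("proteins: %d identified -> %d after >50%% missingness filter\n",
            nrow(protein), nrow(filtered)))

paired <- pair_genes(imputed, mrna)
corr <- correlate_expression(paired, method = "spearman", alpha = 0.01)
cat(sprintf("pairs tested: %d across %d samples\n",
            corr$summary$n_tested, paired$n_samples))
cat(sprintf("median rho: %.3f; significant positive: %d (%.1f%%) at adjusted p < 0.01\n",
            corr$summary$median_rho, corr$summary$n_sig_pos,
            corr$summary$pct_sig_pos))

rho <- with(corr$records, stats::setNames(rho, gene))[!corr$records$flagged]
enrich <- ks_pathway_enrichment(rho, pathways, min_members = 5)
top <- enrich[order(enrich$adj_p), ]
cat("top enriched pathways (mean member rho, adjusted p):\n")
print(utils::head(top[, c("pathway", "mean_score", "adj_p")], 5),
      row.names = FALSE)

out <- "results/analysis"
dir.create(out, recursive = TRUE, showWarnings = FALSE)
utils::write.table(corr$records, file.path(out, "correlation_records.tsv"),
                   sep = "\t", quote = FALSE, row.names = FALSE)
utils::write.table(enrich, file.path(out, "ks_enrichment.tsv"),
                   sep = "\t", quote = FALSE, row.names = FALSE)
write_matrix(imputed, file.path(out, "protein_imputed.tsv"), "gene")
cat("wrote correlation_records.tsv, ks_enrichment.tsv, protein_imputed.tsv\n")
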