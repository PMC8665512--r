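#!/usr/bin/env Rscript
# Step 3 — proteomic subgroup discovery.
#
# Consensus k-medoids clustering of the top 25% most varied proteins,
# Kruskal-Wallis differential expression among the subgroups, association
# with clinicopathologic variables, and microenvironment signature scores.

library(hepamix)

dir <- "results/cohort"; out <- "results/analysis"
imputed <- read_matrix(file.path(out, "protein_imputed.tsv"))
clinical <- read_clinical(file.path(dir, "clinical.csv"))
signatures <- read_gmt(file.path(dir, "signatures.gmt"))
mrna <- read_matrix(file.path(dir, "mrna.tsv"))

variable <- select_variable(imputed, 0.25, "mad")
cat(sprintf("clustering %d high-variance proteins across %d samples\n",
            nrow(variable), ncol(variable)))
cl <- consensus_cluster(variable, k_range = 2:6, n_resamples = 1000,
                        subsample_fraction = 0.8, seed = 21)
print(cl$selection_trace, row.names = FALSE)
cat(sprintf("selected K = %d (minimal PAC); subgroup sizes: %s\n",
            cl$k, paste(table(cl$labels), collapse = "/")))

de <- kw_differential(variable, cl$labels, alpha = 0.05)
cat(sprintf("differentially expressed proteins (BH p < 0.05): %d of %d\n",
            sum(de$significant), nrow(de)))

assoc <- clinical_association(cl$labels, clinical)
cat("clinical association p-values:\n")
print(assoc, row.names = FALSE)

scores <- signature_scores(mrna, signatures)
lab <- cl$labels[scores$sample]
for (sc in c("immune_score", "stroma_score", "microenvironment_score")) {
  kw <- stats::kruskal.test(scores[[sc]], factor(lab))
  cat(sprintf("%s across subgroups: KW p = %.3g\n", sc, kw$p.value))
}

utils::write.table(data.frame(sample = names(cl$labels),
                              subgroup = unname(cl$labels)),
                   file.path(out, "subgroup_labels.tsv"),
                   sep = "\t", quote = FALSE, row.names = FALSE)
utils::write.table(de, file.path(out, "de_subgroups.tsv"),
                   sep = "\t", quote = FALSE, row.names = FALSE)
utils::write.table(scores, file.path(out, "signature_scores.tsv"),
                   sep = "\t", quote = FALSE, row.names = FALSE)
cat("wrote subgroup_labels.tsv, de_subgroups.tsv, signature_scores.tsv\n")
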