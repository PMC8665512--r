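#!/usr/bin/env Rscript
# Step 4 — metabolic pathway activity per proteomic subgroup.
#
# PAS = mean relative abundance (linear scale) of a pathway's proteins
# within a subgroup; 1 = cohort average. Significance by permutation of
# the subgroup labels; non-significant cells are masked as in an activity
# heatmap.

library(hepamix)

out <- "results/analysis"
imputed <- read_matrix(file.path(out, "protein_imputed.tsv"))
labels_df <- utils::read.delim(file.path(out, "subgroup_labels.tsv"))
labels <- stats::setNames(labels_df$subgroup, labels_df$sample)
pathways <- read_gmt("results/cohort/pathways.gmt")

pas <- pathway_activity_score(imputed, labels, pathways, B = 999,
                              alpha = 0.05, seed = 22, input_scale = "log2")
cat(sprintf("pathway-subgroup pairs scored: %d; significant at permutation p <= 0.05: %d\n",
            nrow(pas), sum(pas$significant)))
mat <- pas_heatmap_table(pas, alpha = 0.05)
cat(sprintf("masked (non-significant) cells: %d of %d\n",
            sum(is.na(mat)), length(mat)))
sig <- pas[pas$significant & pas$pas > 1, ]
sig <- sig[order(-sig$pas), ]
cat("strongest activations:\n")
print(utils::head(sig, 6), row.names = FALSE)

utils::write.table(as.data.frame(pas), file.path(out, "pas_long.tsv"),
                   sep = "\t", quote = FALSE, row.names = FALSE)
utils::write.table(data.frame(pathway = rownames(mat), mat,
                              check.names = FALSE),
                   file.path(out, "pas_matrix.tsv"),
                   sep = "\t", quote = FALSE, row.names = FALSE)
cat("wrote pas_long.tsv, pas_matrix.tsv\n")
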