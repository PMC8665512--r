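#!/usr/bin/env Rscript
# Step 7 — cross-omics overlap of the per-stage hit sets.
#
# Venn partition of the significant positive mRNA-protein correlations,
# the subgroup differentially expressed proteins, and the methylation-
# attenuated proteins.

library(hepamix)

out <- "results/analysis"
corr <- utils::read.delim(file.path(out, "correlation_records.tsv"))
de <- utils::read.delim(file.path(out, "de_subgroups.tsv"))
atten <- utils::read.delim(file.path(out, "attenuation.tsv"))

sets <- list(
  positive_correlation = corr$gene[!is.na(corr$adj_p) &
                                     corr$adj_p < 0.01 & corr$rho > 0],
  de_protein = de$feature[de$significant],
  attenuated = atten$gene[atten$attenuated])
cat("set sizes:\n")
print(lengths(sets))
ov <- overlap_summary(sets)
print(ov, row.names = FALSE)

utils::write.table(ov, file.path(out, "overlap_summary.tsv"),
                   sep = "\t", quote = FALSE, row.names = FALSE)
cat("wrote overlap_summary.tsv\n")
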