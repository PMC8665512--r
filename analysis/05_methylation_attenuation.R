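#!/usr/bin/env Rscript
# Step 5 — differential methylation and protein attenuation.
#
# Calls subgroup DMRs on M-values (autosomes only), annotates regions
# against the gene model (promoter / gene body / intergenic), summarizes
# methylation per gene over its DMR links, and classifies proteins whose
# methylation effect reaches mRNA but not protein with a two-component
# Gaussian mixture over correlation differences.

library(hepamix)

dir <- "results/cohort"; out <- "results/analysis"
meth <- read_matrix(file.path(dir, "methylation.tsv"), "beta")
regions <- read_regions(file.path(dir, "regions.tsv"))
gene_model <- read_gene_model(file.path(dir, "gene_model.tsv"))
mrna <- read_matrix(file.path(dir, "mrna.tsv"))
imputed <- read_matrix(file.path(out, "protein_imputed.tsv"))
pathways <- read_gmt(file.path(dir, "pathways.gmt"))
labels_df <- utils::read.delim(file.path(out, "subgroup_labels.tsv"))
labels <- stats::setNames(labels_df$subgroup, labels_df$sample)

dmrs <- call_dmrs(meth, regions, labels, alpha = 0.05, min_delta = 0.1)
cat(sprintf("DMRs among subgroups: %d of %d autosomal regions\n",
            sum(dmrs$dmr), nrow(dmrs)))
ann <- annotate_regions(regions, gene_model, promoter_window = 1500)
dmr_ann <- merge(dmrs[dmrs$dmr, c("region_id", "adj_p", "max_delta_beta")],
                 ann[, c("region_id", "annotation", "linked_gene")],
                 by = "region_id")
cat("DMR genomic context:\n")
print(table(dmr_ann$annotation))

links <- dmr_ann[dmr_ann$annotation %in% c("promoter", "gene_body"), ]
atten <- attenuation_gmm(meth, mrna, imputed, links)
cat(sprintf("genes analyzed (>=1 linked DMR): %d; attenuated: %d (%.1f%%)\n",
            atten$summary$n_analyzed, atten$summary$n_attenuated,
            atten$summary$pct_attenuated))
cat(sprintf("mixture components: background N(%.2f, %.2f), attenuated N(%.2f, %.2f)\n",
            min(atten$fit$means), atten$fit$sds[which.min(atten$fit$means)],
            max(atten$fit$means), atten$fit$sds[which.max(atten$fit$means)]))

ora <- hypergeom_ora(atten$records$gene[atten$records$attenuated],
                     atten$records$gene, pathways)
cat("attenuated-set over-representation (top 5):\n")
print(utils::head(ora[order(ora$adj_p), ], 5), row.names = FALSE)

utils::write.table(dmrs, file.path(out, "dmrs.tsv"),
                   sep = "\t", quote = FALSE, row.names = FALSE)
utils::write.table(dmr_ann, file.path(out, "dmrs_annotated.tsv"),
                   sep = "\t", quote = FALSE, row.names = FALSE)
utils::write.table(atten$records, file.path(out, "attenuation.tsv"),
                   sep = "\t", quote = FALSE, row.names = FALSE)
utils::write.table(ora, file.path(out, "attenuated_ora.tsv"),
                   sep = "\t", quote = FALSE, row.names = FALSE)
cat("wrote dmrs.tsv, dmrs_annotated.tsv, attenuation.tsv, attenuated_ora.tsv\n")
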