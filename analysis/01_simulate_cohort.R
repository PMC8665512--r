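#!/usr/bin/env Rscript
# Step 1 — generate the reference synthetic cohort.
#
# 77 noncancerous liver samples with three latent proteomic subgroups, a
# planted positively-correlated metabolic gene subset, methylation-
# attenuated genes, subgroup-dependent relapse hazards and MS-style
# protein missingness. All downstream steps read the files written here.

library(hepamix)

spec <- cohort_spec(seed = 20)
cohort <- simulate_cohort(spec)
print(cohort)

dir <- "results/cohort"
manifest <- write_cohort(cohort, dir)
cat("wrote", nrow(manifest), "files to", dir, "\n")

cat(sprintf("samples: %d  genes: %d  regions: %d  pathways: %d\n",
            spec$n_samples, spec$n_genes, nrow(cohort$regions),
            length(cohort$pathways$genes)))
cat(sprintf("protein missingness: %.1f%% (budget: MCAR %.0f%% + dropout on the lowest decile)\n",
            100 * mean(is.na(cohort$protein)),
            100 * spec$missing_rate_protein))
cat(sprintf("planted: %d correlated, %d attenuated, %d marker genes; %d active pathway-subgroup pairs\n",
            length(cohort$truth$positively_correlated_genes),
            length(cohort$truth$attenuated_genes),
            length(cohort$truth$marker_genes),
            sum(lengths(cohort$truth$active_pathways_by_subgroup))))
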