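#!/usr/bin/env Rscript
# Step 6 — recurrence-free survival and prognostic markers.
#
# Early-relapse proportions per subgroup (Fisher, pairwise and TNM-
# stratified), Kaplan-Meier / log-rank within 24 months, multivariable Cox
# adjusted for clinicopathologic factors, and the supervised MI/MA marker
# screen.

library(hepamix)

dir <- "results/cohort"; out <- "results/analysis"
clinical <- read_clinical(file.path(dir, "clinical.csv"))
imputed <- read_matrix(file.path(out, "protein_imputed.tsv"))
labels_df <- utils::read.delim(file.path(out, "subgroup_labels.tsv"))
labels <- stats::setNames(labels_df$subgroup, labels_df$sample)

flags <- early_relapse_flag(clinical, horizon_months = 24)[names(labels)]
cat(sprintf("early relapse: %d yes, %d no, %d indeterminate (censored < 24 m)\n",
            sum(flags == 1, na.rm = TRUE), sum(flags == 0, na.rm = TRUE),
            sum(is.na(flags))))
prop <- relapse_proportion_test(flags, labels)
cat("pairwise early-relapse Fisher tests:\n")
print(prop, row.names = FALSE)
tnm <- stats::setNames(clinical$tnm_stage, clinical$sample)
prop_strat <- relapse_proportion_test(flags, labels,
                                      strata = tnm[names(labels)])

km <- km_logrank(clinical, labels, horizon_months = 24)
cat(sprintf("log-rank over subgroups (24-month horizon): chi-square %.2f, df %d, p = %.3g\n",
            km$chisq, km$df, km$p))
cox <- cox_multivariable(clinical, labels,
                         covariates = c("tnm_stage", "afp_high", "thrombus"),
                         horizon_months = 24)
cat("multivariable Cox (subgroup indicators + clinicopathologic factors):\n")
print(cox$coefficients, row.names = FALSE)

markers <- marker_screen(imputed, clinical, alpha = 0.05)
cat(sprintf("marker screen: %d MI/MA hits, %d passing log-rank and Cox\n",
            attr(markers, "n_stage1_hits"), sum(markers$passed)))
print(markers[markers$passed, ], row.names = FALSE)

utils::write.table(prop, file.path(out, "relapse_proportion.tsv"),
                   sep = "\t", quote = FALSE, row.names = FALSE)
utils::write.table(prop_strat,
                   file.path(out, "relapse_proportion_stratified.tsv"),
                   sep = "\t", quote = FALSE, row.names = FALSE)
utils::write.table(km$curves, file.path(out, "km_curves.tsv"),
                   sep = "\t", quote = FALSE, row.names = FALSE)
utils::write.table(cox$coefficients, file.path(out, "cox_coefficients.tsv"),
                   sep = "\t", quote = FALSE, row.names = FALSE)
utils::write.table(markers, file.path(out, "marker_screen.tsv"),
                   sep = "\t", quote = FALSE, row.names = FALSE)
cat("wrote relapse/KM/Cox/marker tables\n")
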