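# hepamix

Proteogenomic integration of multi-omics cohorts from noncancerous liver
tissue of liver-cancer surgery patients. The package asks how much of the
proteome is explained by the transcriptome and the methylome in the
tumor-adjacent liver, whether the proteome stratifies patients into
subgroups with distinct metabolic activity, and whether those subgroups
carry prognostic information about early relapse. It is written for
computational biologists analyzing matched TMT proteome / RNA-seq /
methylation cohorts, and ships a seeded synthetic cohort generator so the
whole workflow can be exercised against known ground truth.

## What it computes

- **mRNA–protein correlation screen.** Per gene *g*, the Spearman
  correlation ρ<sub>g</sub> of transcript and protein abundance across
  samples, two-sided p-values with Benjamini–Hochberg control; the
  "significant positive" set is {adj p < 0.01, ρ > 0}. Pathway structure in
  the ranked ρ list is tested with a two-sample Kolmogorov–Smirnov test of
  member vs non-member correlations.
- **Proteomic subgroups.** Consensus clustering (k-medoids over 1,000
  resampled 80% sample subsets, 1 − Spearman distance on z-scored
  features) of the top 25% most varied proteins; the number of subgroups
  minimizes the proportion of ambiguous clustering (PAC). Differential
  expression among subgroups uses tie-corrected Kruskal–Wallis tests with
  BH control; clinical associations use Fisher's exact test.
- **Pathway activity score (PAS).** On the linear scale, the relative
  abundance of gene *g* in sample *i* is x<sub>gi</sub> / mean<sub>i</sub>
  x<sub>gi</sub>; PAS(pathway *j*, subgroup *c*) is the mean relative
  abundance of *j*'s genes over *c*'s samples, so 1 is cohort-average
  activity. Significance comes from B = 999 permutations of the subgroup
  labels, two-sided around 1; this preserves the gene–gene covariance.
- **Methylation attenuation.** Subgroup DMRs are called per region with
  Kruskal–Wallis tests on M-values (autosomes only, BH-adjusted, plus a
  minimum 0.1 beta difference), annotated as promoter / gene body /
  intergenic against a gene model. Per DMR-linked gene, the attenuation
  score is r(meth, protein) − r(meth, mRNA); a two-component Gaussian
  mixture fit by EM separates background from attenuated proteins — genes
  where methylation's negative effect reaches the transcript but is damped
  at the protein.
- **Recurrence-free survival.** Early relapse = recurrence within 24
  months; subgroup proportions compared pairwise with Fisher's exact test
  (also TNM-stratified), Kaplan–Meier curves with the log-rank test,
  multivariable Cox (Efron ties) adjusted for TNM stage, AFP and tumor
  thrombus, and a three-stage supervised MI/MA marker screen (rank-sum →
  median-split log-rank → adjusted Cox).

## Worked example

The numbered scripts under `analysis/` run the whole workflow on the
reference synthetic cohort (77 samples, 2,000 genes, 3,000 methylation
regions, 30 pathways):

```sh
Rscript analysis/01_simulate_cohort.R
Rscript analysis/02_correlation_screen.R
...
Rscript analysis/07_overlap_report.R
```

Step 2 prints, for the default seed:

```
pairs tested: 2000 across 77 samples
median rho: 0.033; significant positive: 311 (15.6%) at adjusted p < 0.01
```

— the cohort-wide correlation sits near zero (most of the proteome is
post-transcriptionally shaped) while a planted metabolic subset correlates
strongly; the KS screen finds exactly those pathways (mean member ρ ≈
0.53–0.57, adjusted p < 1e-8). Step 3 selects K = 3 subgroups with PAC = 0
(sizes 26/25/26) and 274 of 500 high-variance proteins differentially
expressed. Step 4 masks 53 of 90 pathway × subgroup activity cells as
non-significant and reports the planted activations (PAS ≈ 1.2–1.4,
permutation p = 0.001). Step 5 calls 1,442 DMRs (majority intergenic among
the extra-genic regions), and the attenuation mixture classifies 362 of
877 DMR-linked proteins (41.3%) as attenuated, with component means ≈ 0
and 0.77. Step 6 finds the high-hazard subgroup's early-relapse proportion
significantly different from the other two (Fisher p < 1e-3) and a
24-month log-rank chi-square of 31.3 (p ≈ 2e-7), confirmed by
multivariable Cox.

A single call runs everything from one config:

```r
library(hepamix)
report <- run_pipeline(list(
  seed = 7, output_dir = "results/report",
  inputs = list(protein = "protein.tsv", mrna = "mrna.tsv",
                clinical = "clinical.csv", pathways = "pathways.gmt",
                methylation = "methylation.tsv", regions = "regions.tsv",
                gene_model = "gene_model.tsv")))
```

Every stage logs its input/output counts; branches with missing inputs
(e.g. no methylation) are skipped with a logged reason.

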