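---
title: "Methods: proteogenomic integration of a multi-omics liver cohort"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: proteogenomic integration of a multi-omics liver cohort}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hepamix)
```

This vignette documents the models and procedures behind `hepamix`, the
assumptions they make, the tunable parameters and their defaults, what the
synthetic cohort generator does and does not emulate, and the numerical
choices a maintainer would want written down.

## The scientific setting

Matched cohorts of tumor-adjacent ("noncancerous") liver tissue carry
three omics layers: a TMT mass-spectrometry proteome (log2 abundance with
structured missingness), an RNA-seq transcriptome (log2 expression), and
region-level DNA methylation (beta values in [0, 1]). The questions the
pipeline addresses, in order: how tightly protein tracks mRNA per gene;
whether the proteome partitions the cohort into stable subgroups; whether
those subgroups differ in metabolic pathway activity; whether methylation
effects on transcripts are buffered before they reach the protein; and
whether the subgroups predict early relapse after surgery.

## mRNA–protein correlation

Gene identity is a single shared symbol namespace; pairing is by exact
symbol match (`pair_genes()`), an assumption that protein isoforms were
already collapsed to gene symbols upstream. Correlation defaults to
Spearman: cross-omic abundance scales are not comparable, and a rank
statistic is exactly invariant to each platform's monotone distortions
(this invariance is asserted in the tests). Two-sided p-values are
BH-adjusted across all testable genes; genes with a constant vector or
fewer than 3 complete pairs are flagged and excluded from the BH
denominator rather than silently given p = 1.

Pathway enrichment over the ranked correlations uses a **two-sample**
Kolmogorov–Smirnov test of member vs non-member scores. A one-sample
variant against a theoretical null was rejected because the cohort-wide
correlation distribution is itself the natural reference. Pathways with
fewer than `min_members = 5` scored genes, or whose complement is empty,
are skipped (not scored 0) — a two-sample statistic is undefined there.

## Preprocessing

* `filter_missing()` removes proteins missing in **strictly more than**
  `max_missing_fraction = 0.5` of the samples: with 77 samples a protein
  missing in 39 (50.6%) is removed and one missing in 38 (49.4%) is kept.
* `impute_missing()` defaults to a shifted-minimum rule (per-feature
  minimum observed − 1 log2 unit), reflecting that MS dropout is
  abundance-biased, so a low imputed value is the best least-commitment
  guess; it is deterministic, which end-to-end reproducibility relies on.
  A `knn` alternative averages regression predictions from the k most
  correlated features; with a single perfectly correlated neighbor it
  reproduces the neighbor's affine prediction exactly. Observed cells are
  never modified by either method.
* `select_variable()` keeps `ceiling(0.25 × n)` features by MAD (robust to
  the heavy tails of TMT ratios; SD offered as an alternative), with ties
  at the cutoff broken lexicographically by feature ID so selection is
  deterministic.

Note the fraction applies to the current input, so the selection step is
not idempotent in the strict sense (re-selecting 25% of a 25% selection
keeps 6.25%); filtering and imputation are idempotent, and re-selecting
the selected output with fraction 1 is the identity.

## Consensus subgroups

Features are z-scored; the sample–sample distance is 1 − Spearman
correlation, the proteomics convention that makes distances insensitive
to per-sample scaling. For each candidate K, 1,000 k-medoids runs on
random 80% sample subsets are aggregated into a consensus matrix of
co-clustering frequencies among co-sampled pairs; final labels cut an
average-linkage tree of 1 − consensus.

K is selected by **minimal PAC** (proportion of consensus entries in
(0.1, 0.9)). We first implemented the consensus-CDF area-gain rule; on
planted 3-subgroup data it reproducibly selects K = 2, because two of the
three clusters merge *stably* under subsampling — the area at K = 2 is
already large and the relative gain at 3 cannot beat it. PAC measures
exactly the property consensus clustering is after (every pair either
always or never co-clusters) and attains 0 at the planted K; ties go to
the smaller K. The selection trace reports PAC, area and area gain so the
choice is auditable.

## Pathway activity score

PAS is computed on the **linear** scale (log2 input is exponentiated;
ratios of log values are not meaningful): relative abundance of gene g =
value / cohort mean of g, and PAS(j, c) = mean relative abundance of
pathway j's genes over subgroup c's samples. Two consequences are
asserted numerically in the tests: the subgroup-size-weighted mean PAS is
1 for every pathway (conservation, to 1e-10), and multiplying any gene's
abundances by a positive constant leaves PAS unchanged (scale freedom).
The unweighted mean over genes is the tested default; no outlier trimming
is applied.

The null permutes **sample labels** (B = 999), preserving the gene–gene
covariance that a gene-level null would destroy; p = (1 + #{|PAS' − 1| ≥
|PAS − 1|}) / (B + 1), two-sided around 1, so the smallest attainable p is
1/(B+1). Subgroups below 3 samples are an error, not a warning — a
1-sample "subgroup" would make PAS a single relative abundance.

## Methylation and attenuation

DMR calling clips betas to [0.001, 0.999], transforms to M-values
(logit2), and runs per-region Kruskal–Wallis tests across subgroups with
BH control; a DMR additionally needs a maximum pairwise mean-beta
difference of at least `min_delta = 0.1`, a conventional floor that
blocks statistically significant but biologically negligible shifts.
Sex-chromosome regions are dropped up front (autosomes only). Annotation
uses 0-based half-open intervals throughout: promoter = overlap with
[TSS − 1500, TSS + 1500) on the gene's strand, else gene body, else
intergenic; promoter wins over gene body and multi-gene overlaps resolve
to the nearest TSS. The boundary semantics are pinned by a test (a 1-bp
region exactly at TSS + window is *not* promoter).

The attenuation statistic per DMR-linked gene is
r(meth, protein) − r(meth, mRNA), both Spearman, with methylation
summarized as the mean beta over the gene's linked regions. When
methylation's negative effect reaches the transcript but not the protein,
the first term sits near 0 and the second is negative, so attenuated
genes score high. A two-component univariate Gaussian mixture is fit to
all scores by EM: deterministic initialization at the means of the lowest
and highest quartiles, equal weights, pooled SD; convergence at 1e-8 on
the log-likelihood, at most 1,000 iterations; the log-likelihood is
checked to be non-decreasing at every iteration. The attenuated component
is the one with the larger mean and genes are called at posterior ≥ 0.5
(maximum a posteriori; a stricter cutoff can be passed). Degenerate fits
(component weight < 0.01, SD < 1e-6, or constant input) fall back to a
single component with zero attenuated genes and a flag — a silent
two-component fit on such data would be noise. Fewer than 20 analyzable
genes is an error: the mixture is not identifiable at toy sizes.
Intergenic DMRs are counted but never linked to genes (no enhancer map is
in scope).

## Survival

Early relapse is an event within 24 months. Samples censored before the
horizon without an event are **indeterminate** and excluded from the
Fisher proportion tests — the only handling that uses no unobserved
information. Proportion tests are pairwise (and TNM-stratified on
request) rather than an omnibus R×C test, matching the question "is this
subgroup's early-relapse rate different from that one's". Kaplan–Meier /
log-rank run with administrative censoring at the horizon (which can only
convert events to censorings, never create events). Cox regression uses
Efron tie handling — months-resolution follow-up guarantees ties — with
TNM stage entered as an ordinal integer, and AFP and thrombus as
binaries; perfect separation is detected and reported as an error naming
the covariate. The marker screen passes a protein only if it clears all
three stages at the chosen level: MI vs MA rank-sum (BH), median-split
log-rank (ties assigned to the low group), and the adjusted Cox model.

## The synthetic cohort generator

`cohort_spec()` / `simulate_cohort()` define the study conditions: 77
samples in 3 latent subgroups (equal proportions by default), 2,000 genes,
3,000 regions, 30 pathways. On the log2 scale, per gene g and sample i:

* mRNA = baseline + immune-signature subgroup shift (mRNA only) −
  k<sub>g</sub> · (beta − mean beta) + noise, with k<sub>g</sub> = 3 for
  attenuated genes (20% of genes) and 0 otherwise;
* protein = baseline + subgroup shift (informative genes, SD 1.0 log2
  units ≈ 2 within-group noise SDs) + pathway activation (log2 1.5 for a
  subgroup's active pathways) + w<sub>g</sub> · (mRNA noise component) +
  noise, where w<sub>g</sub> is solved from the bivariate-normal relation
  ρ<sub>Pearson</sub> = 2 sin(π ρ<sub>Spearman</sub>/6) so planted genes
  (16% of genes) hit the target Spearman 0.6 in expectation and everything
  else sits at 0;
* methylation betas are a logistic transform of a Gaussian latent (SD
  0.8) with subgroup shifts (SD 1.5) on planted DMRs: the promoters of
  attenuated genes, a third of other promoters (subgroup-variable
  methylation that does not couple to expression), and 60% of intergenic
  regions;
* recurrence times are exponential with subgroup hazards (0.010, 0.060,
  0.025 events/month — the middle subgroup is the high-risk one), an
  extra hazard ratio of 2 for MI-phenotype samples, and exponential
  censoring (0.010/month) truncated at 60 months; times are rounded to
  0.1 month, which deliberately produces the ties Efron's correction is
  for;
* protein entries go missing completely at random at 5% plus 20% extra
  dropout on the lowest abundance decile, emulating intensity-dependent
  MS dropout; the expected missing fraction r + 0.1·0.2·(1−r) is asserted
  in the tests.

Gene roles (correlated / attenuated / subgroup-informative / MI-MA
markers / cell-type signatures) are disjoint blocks. Planted-correlation
genes carry no subgroup shift — subgroup structure in the protein would
otherwise leak into every gene's mRNA–protein correlation and lift the
background off zero. A quarter of the pathways are built from the
correlated genes (so the KS stage has a true positive to find) and are
never the activated ones (so activation cannot perturb the correlation
calibration).

None of the effect sizes or noise levels are estimates of any real
cohort — the source data are not public — so passing tests show the
*procedures* are correct and well calibrated under a plausible generative
model, not that the numbers transfer to real tissue. The generator also
does not emulate TMT batch (plex) structure, isoform ambiguity,
copy-number variation, enhancer-linked methylation, or tumor-tissue
profiles.

## Reproducibility and problem sizes

Every stochastic stage takes a seed, and `run_pipeline()` fans one global
seed out by fixed offsets so single stages can be rerun in isolation;
RNG state is always restored afterwards. Identical config + seed gives
byte-identical report tables (asserted by checksum in the tests). The
test suite runs the clustering recovery at 77 samples with 250 resamples,
the permutation calibration at ~1,000 pathway × subgroup pairs with
B = 999, and the attenuation sensitivity/specificity at 2,000 genes over
10 seeds — sizes chosen so the whole suite completes in about a minute
while keeping every statistical check at its stated operating point.

## Known limitations

* The cluster-number search is bounded (default K in 2–6) and PAC can be
  flat when no structure exists; the selection trace should be inspected.
* KNN imputation is O(features²) in the worst case and is meant for
  moderate panels, not proteome-wide holes; the default shifted-minimum
  rule is the tested path.
* The attenuation mixture assumes two Gaussian components; heavy-tailed
  score distributions (e.g. from very few shared samples) can inflate the
  background SD and cost sensitivity.
* The microenvironment scores are mean z-scores per signature with
  immune/stroma sums — a deliberately simple aggregate with no spillover
  compensation between correlated cell types.
* Exact R×C Fisher tests fall back to chi-square above 500 samples
  (flagged in the output).
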