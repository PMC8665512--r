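# Seeded synthetic multi-omics cohort generator. Emulates a surgical liver
# cohort: a TMT-style protein matrix with structured missingness, paired
# RNA-seq, region-level methylation driving a subset of transcripts,
# three latent proteomic subgroups with distinct metabolic pathway activity
# and relapse hazards, and a clinical table.

#' Specify a synthetic cohort
#'
#' All downstream analyses are exercised against cohorts drawn from this
#' generative model. Defaults describe the reference study conditions:
#' 77 samples, 3 latent subgroups, a metabolic-gene subset with planted
#' positive mRNA-protein correlation over a near-zero background, a planted
#' fraction of methylation-attenuated genes, and subgroup-dependent relapse
#' hazards.
#'
#' Gene roles are disjoint blocks: planted-correlation genes carry no
#' subgroup shift (so the background correlation stays near zero),
#' attenuated genes couple methylation into mRNA but not protein,
#' informative genes carry protein-level subgroup shifts, marker genes
#' separate the MI/MA phenotype, and signature genes carry mRNA-level
#' immune shifts.
#'
#' @param n_samples Cohort size (default 77).
#' @param n_genes Number of genes (shared namespace across omics).
#' @param n_regions Number of methylation regions (>= `n_genes` promoter
#'   regions are linked one-per-gene; the remainder are intergenic).
#' @param n_pathways Number of metabolic pathways emitted to the GMT.
#' @param subgroup_proportions Length-3 simplex vector of subgroup sizes.
#' @param corr_gene_fraction Fraction of genes with planted positive
#'   mRNA-protein correlation.
#' @param target_rho_pos Target Spearman correlation for planted genes.
#' @param attenuated_fraction Fraction of genes whose methylation effect
#'   reaches mRNA but not protein.
#' @param hazard_by_subgroup Exponential relapse hazards (events/month).
#' @param censor_rate Exponential censoring rate (events/month).
#' @param thrombus_prob_by_subgroup Tumor-thrombus probability per subgroup.
#' @param missing_rate_protein Completely-at-random protein missingness.
#' @param seed Integer seed; identical seeds give byte-identical cohorts.
#' @param sd_baseline,sd_mrna_noise,sd_protein_noise Gaussian SDs of the
#'   per-gene baseline and per-entry noise (log2 units).
#' @param subgroup_shift SD of protein subgroup mean shifts for informative
#'   genes (log2 units).
#' @param informative_fraction Fraction of genes that are subgroup-informative.
#' @param pathway_activation Linear fold-activation of active pathways in
#'   their subgroup (protein level).
#' @param n_active_pathways_per_subgroup Active pathways planted per subgroup.
#' @param pathway_size Genes per pathway.
#' @param meth_effect Log2-mRNA change per unit beta for attenuated genes.
#' @param sd_meth_latent SD of the methylation latent Gaussian.
#' @param dmr_shift SD of subgroup shifts on planted DMR latents.
#' @param promoter_dmr_fraction Fraction of non-attenuated promoters with
#'   subgroup-variable methylation that does not couple to expression.
#' @param intergenic_dmr_fraction Fraction of intergenic regions planted as
#'   DMRs.
#' @param low_abundance_extra Extra missingness probability on the lowest
#'   abundance decile (mass-spectrometry-style intensity-dependent dropout).
#' @param mi_prob_by_subgroup Probability of the metastasis-inclined (MI)
#'   phenotype per subgroup.
#' @param phenotype_hr Relapse hazard ratio of MI vs MA samples (the
#'   metastasis-inclined microenvironment carries its own excess hazard on
#'   top of the subgroup hazard).
#' @param phenotype_missing_rate Fraction of samples with unknown phenotype.
#' @param n_marker_genes,marker_effect Planted MI/MA protein markers and
#'   their log2 effect.
#' @param afp_prob_by_subgroup Probability of high AFP per subgroup.
#' @param stage_probs_by_subgroup 3 x 4 matrix of TNM stage probabilities.
#' @param immune_hot_subgroup Subgroup with elevated immune signatures.
#' @param immune_shift mRNA shift of immune signature genes in that subgroup.
#' @param signature_size Genes per cell-type signature.
#' @param max_followup_months Administrative end of follow-up.
#' @return A validated `cohort_spec` list.
#' @export
cohort_spec <- function(n_samples = 77,
                        n_genes = 2000,
                        n_regions = 3000,
                        n_pathways = 30,
                        subgroup_proportions = c(1, 1, 1) / 3,
                        corr_gene_fraction = 0.16,
                        target_rho_pos = 0.6,
                        attenuated_fraction = 0.2,
                        hazard_by_subgroup = c(0.010, 0.060, 0.025),
                        censor_rate = 0.010,
                        thrombus_prob_by_subgroup = c(0.15, 0.30, 0.60),
                        missing_rate_protein = 0.05,
                        seed = 1L,
                        sd_baseline = 1,
                        sd_mrna_noise = 0.5,
                        sd_protein_noise = 0.5,
                        subgroup_shift = 1.0,
                        informative_fraction = 0.15,
                        pathway_activation = 1.5,
                        n_active_pathways_per_subgroup = 2,
                        pathway_size = 15,
                        meth_effect = 3,
                        sd_meth_latent = 0.8,
                        dmr_shift = 1.5,
                        promoter_dmr_fraction = 0.33,
                        intergenic_dmr_fraction = 0.6,
                        low_abundance_extra = 0.2,
                        mi_prob_by_subgroup = c(0.15, 0.70, 0.35),
                        phenotype_hr = 2,
                        phenotype_missing_rate = 0.05,
                        n_marker_genes = 5,
                        marker_effect = 1.5,
                        afp_prob_by_subgroup = c(0.20, 0.30, 0.60),
                        stage_probs_by_subgroup = rbind(
                          c(0.40, 0.35, 0.20, 0.05),
                          c(0.35, 0.35, 0.20, 0.10),
                          c(0.15, 0.30, 0.35, 0.20)),
                        immune_hot_subgroup = 3,
                        immune_shift = 1.0,
                        signature_size = 10,
                        max_followup_months = 60) {
  spec <- as.list(environment())
  class(spec) <- "cohort_spec"
  validate_cohort_spec(spec)
  spec
}

validate_cohort_spec <- function(spec) {
  with(spec, {
    counts <- c(n_samples = n_samples, n_genes = n_genes,
                n_regions = n_regions, n_pathways = n_pathways)
    if (any(counts < 1) || any(counts != round(counts)))
      stop("cohort_spec: counts must be positive integers")
    if (length(subgroup_proportions) != 3 || any(subgroup_proportions <= 0) ||
        abs(sum(subgroup_proportions) - 1) > 1e-12)
      stop("cohort_spec: subgroup_proportions must be a length-3 simplex vector")
    fr <- c(corr_gene_fraction, attenuated_fraction, informative_fraction,
            intergenic_dmr_fraction, phenotype_missing_rate)
    if (any(fr < 0 | fr > 1)) stop("cohort_spec: fractions must lie in [0, 1]")
    if (missing_rate_protein < 0 || missing_rate_protein >= 1 ||
        low_abundance_extra < 0 || low_abundance_extra >= 1)
      stop("cohort_spec: missingness rates must lie in [0, 1)")
    pr <- c(thrombus_prob_by_subgroup, mi_prob_by_subgroup,
            afp_prob_by_subgroup)
    if (any(pr < 0 | pr > 1)) stop("cohort_spec: probabilities must lie in [0, 1]")
    if (length(hazard_by_subgroup) != 3 || any(hazard_by_subgroup <= 0))
      stop("cohort_spec: hazard_by_subgroup must be 3 positive rates")
    if (censor_rate <= 0) stop("cohort_spec: censor_rate must be positive")
    if (phenotype_hr <= 0) stop("cohort_spec: phenotype_hr must be positive")
    if (target_rho_pos <= 0 || target_rho_pos > 1)
      stop("cohort_spec: target_rho_pos must lie in (0, 1]")
    if (corr_gene_fraction > 0 && corr_gene_fraction * n_genes < 1)
      stop("cohort_spec: corr_gene_fraction * n_genes < 1 (no gene to plant)")
    if (attenuated_fraction > 0 && attenuated_fraction * n_genes < 1)
      stop("cohort_spec: attenuated_fraction * n_genes < 1 (no gene to plant)")
    n_roles <- round(corr_gene_fraction * n_genes) +
      round(attenuated_fraction * n_genes) +
      round(informative_fraction * n_genes) +
      n_marker_genes + 8 * signature_size
    if (n_roles > n_genes)
      stop("cohort_spec: gene role blocks exceed n_genes (", n_roles, " > ",
           n_genes, ")")
    if (n_pathways - round(n_pathways / 4) < 3 * n_active_pathways_per_subgroup)
      stop(paste0("cohort_spec: need n_pathways (net of the correlated-gene",
                  " quarter) >= 3 * n_active_pathways_per_subgroup"))
    n_prom <- min(n_genes, n_regions)
    if (round(corr_gene_fraction * n_genes) +
        round(attenuated_fraction * n_genes) > n_prom)
      stop("cohort_spec: not enough promoter regions to cover planted genes")
    if (n_regions - n_prom > 30 * n_prom)
      stop("cohort_spec: too many intergenic regions for the synthetic genome")
    invisible(NULL)
  })
}

# Deterministic subgroup counts by largest remainder, then shuffled.
subgroup_counts <- function(n, prop) {
  base <- floor(n * prop)
  rem <- n - sum(base)
  if (rem > 0) {
    extra <- order(n * prop - base, decreasing = TRUE)[seq_len(rem)]
    base[extra] <- base[extra] + 1
  }
  base
}

#' Simulate a multi-omics cohort
#'
#' Draws a cohort from the generative model in [cohort_spec()]: on the log2
#' scale, `mrna[g,i] = b_g + u_rna - k_g * (beta[g,i] - mean) + e`,
#' `protein[g,i] = b_g + u_prot + w_g * e + f`, where `w_g` is tuned so
#' planted genes reach the target Spearman correlation and background genes
#' sit near zero; for attenuated genes the methylation term reaches mRNA
#' (`k_g > 0`) but not protein. Methylation betas are a logistic transform
#' of a Gaussian latent with subgroup shifts on planted DMRs. Active
#' pathways receive a protein-level fold-activation in their subgroup.
#' Recurrence times are exponential with subgroup hazards and exponential
#' censoring. Protein entries go missing completely at random plus extra
#' dropout on the lowest abundance decile.
#'
#' @param spec A [cohort_spec()].
#' @return A list of class `synthetic_cohort` with elements `protein`,
#'   `mrna`, `methylation` (omics matrices), `regions`, `gene_model`,
#'   `clinical` (data.frames), `pathways`, `signatures` (pathway DBs),
#'   `truth` (ground-truth labels and planted sets) and `spec`.
#' @export
simulate_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  validate_cohort_spec(spec)
  with_rng_seed(spec$seed, simulate_cohort_impl(spec))
}

simulate_cohort_impl <- function(spec) {
  s <- spec
  n <- s$n_samples
  G <- s$n_genes
  genes <- sprintf("GENE%05d", seq_len(G))
  samples <- sprintf("S%03d", seq_len(n))

  ## --- gene roles (disjoint blocks) ---------------------------------------
  n_corr <- round(s$corr_gene_fraction * G)
  n_att <- round(s$attenuated_fraction * G)
  n_inf <- round(s$informative_fraction * G)
  i_corr <- seq_len(n_corr)
  i_att <- seq_len(n_att) + n_corr
  i_inf <- seq_len(n_inf) + n_corr + n_att
  i_mark <- seq_len(s$n_marker_genes) + n_corr + n_att + n_inf
  i_sig <- seq_len(8 * s$signature_size) + n_corr + n_att + n_inf +
    s$n_marker_genes

  ## --- subgroups and clinical covariates ----------------------------------
  cnt <- subgroup_counts(n, s$subgroup_proportions)
  subgroup <- sample(rep.int(1:3, cnt))
  names(subgroup) <- samples
  phenotype <- ifelse(stats::runif(n) < s$mi_prob_by_subgroup[subgroup],
                      "MI", "MA")
  phenotype[stats::runif(n) < s$phenotype_missing_rate] <- NA_character_
  tnm <- vapply(subgroup, function(c)
    sample(c("I", "II", "III", "IV"), 1,
           prob = s$stage_probs_by_subgroup[c, ]), "")
  afp <- stats::rbinom(n, 1, s$afp_prob_by_subgroup[subgroup])
  thrombus <- stats::rbinom(n, 1, s$thrombus_prob_by_subgroup[subgroup])
  is_mi <- !is.na(phenotype) & phenotype == "MI"
  t_ev <- stats::rexp(n, rate = s$hazard_by_subgroup[subgroup] *
                        ifelse(is_mi, s$phenotype_hr, 1))
  t_cn <- pmin(stats::rexp(n, rate = s$censor_rate), s$max_followup_months)
  rfs_event <- as.integer(t_ev <= t_cn)
  rfs_months <- round(pmin(t_ev, t_cn), 1)
  clinical <- data.frame(sample = samples, rfs_months = rfs_months,
                         rfs_event = rfs_event, tnm_stage = tnm,
                         afp_high = afp, thrombus = thrombus,
                         phenotype = phenotype, stringsAsFactors = FALSE)
  validate_clinical(clinical)

  ## --- genome layout: genes and regions (0-based half-open) ---------------
  n_prom <- min(G, s$n_regions)
  n_intergenic <- s$n_regions - n_prom
  chrom_idx <- ((seq_len(G) - 1) %% 22) + 1
  within <- (seq_len(G) - 1) %/% 22
  gene_start <- 1e5 * (within + 1)
  gene_end <- gene_start + 2e4
  strand <- ifelse(seq_len(G) %% 2 == 1, "+", "-")
  tss <- ifelse(strand == "+", gene_start, gene_end - 1)
  gene_model <- data.frame(gene = genes, chrom = paste0("chr", chrom_idx),
                           tss = tss, strand = strand,
                           gene_start = gene_start, gene_end = gene_end,
                           stringsAsFactors = FALSE)

  prom <- data.frame(chrom = gene_model$chrom[seq_len(n_prom)],
                     start = tss[seq_len(n_prom)] - 200,
                     end = tss[seq_len(n_prom)] + 300,
                     region_id = sprintf("REG%05d", seq_len(n_prom)),
                     linked_gene = genes[seq_len(n_prom)],
                     stringsAsFactors = FALSE)
  regions <- prom
  if (n_intergenic > 0) {
    slot <- ((seq_len(n_intergenic) - 1) %% n_prom) + 1
    cycle <- (seq_len(n_intergenic) - 1) %/% n_prom
    ig <- data.frame(chrom = gene_model$chrom[slot],
                     start = gene_end[slot] + 40000 + 1000 * cycle,
                     end = gene_end[slot] + 40000 + 1000 * cycle + 500,
                     region_id = sprintf("REG%05d", n_prom + seq_len(n_intergenic)),
                     linked_gene = NA_character_,
                     stringsAsFactors = FALSE)
    # a handful of sex-chromosome regions, to be dropped by the DMR caller
    if (n_intergenic >= 10) {
      sex <- seq(n_intergenic - 4, n_intergenic)
      ig$chrom[sex] <- "chrX"
    }
    regions <- rbind(regions, ig)
  }

  ## --- methylation: logistic transform of a Gaussian latent ---------------
  R <- nrow(regions)
  mu_r <- stats::rnorm(R, 0, 1)
  # planted DMRs: promoters of attenuated genes, a fraction of other
  # promoters (subgroup-variable methylation that does not couple to
  # expression), and a fraction of autosomal intergenic regions
  dmr_rows <- i_att[i_att <= n_prom]
  other_prom <- setdiff(seq_len(n_prom), i_att)
  n_other <- round(s$promoter_dmr_fraction * length(other_prom))
  if (n_other > 0) dmr_rows <- c(dmr_rows, sample(other_prom, n_other))
  if (n_intergenic > 0) {
    ig_rows <- n_prom + seq_len(n_intergenic)
    ig_rows <- ig_rows[regions$chrom[ig_rows] != "chrX"]
    n_ig_dmr <- round(s$intergenic_dmr_fraction * length(ig_rows))
    if (n_ig_dmr > 0) dmr_rows <- c(dmr_rows, sample(ig_rows, n_ig_dmr))
  }
  shift_r <- matrix(0, R, 3)
  if (length(dmr_rows) > 0) {
    shift_r[dmr_rows, ] <- matrix(stats::rnorm(length(dmr_rows) * 3, 0,
                                               s$dmr_shift),
                                  length(dmr_rows), 3)
  }
  latent <- mu_r + shift_r[, subgroup] +
    matrix(stats::rnorm(R * n, 0, s$sd_meth_latent), R, n)
  beta <- stats::plogis(latent)
  dimnames(beta) <- list(regions$region_id, samples)

  ## --- mRNA and protein ----------------------------------------------------
  b <- stats::rnorm(G, 8, s$sd_baseline)
  e <- matrix(stats::rnorm(G * n, 0, s$sd_mrna_noise), G, n)
  k <- numeric(G)
  k[i_att] <- s$meth_effect
  meth_gene <- matrix(0, G, n)  # centered promoter beta per gene
  if (n_prom > 0) {
    pm <- beta[seq_len(n_prom), , drop = FALSE]
    meth_gene[seq_len(n_prom), ] <- pm - rowMeans(pm)
  }
  u_rna <- matrix(0, G, n)
  imm_types <- seq_len(4)  # first 4 signature blocks are immune cell types
  imm_genes <- i_sig[rep(seq_len(8), each = s$signature_size) %in% imm_types]
  hot <- subgroup == s$immune_hot_subgroup
  u_rna[imm_genes, hot] <- s$immune_shift
  mrna <- b + u_rna - k * meth_gene + e

  # protein subgroup shifts: informative genes + active-pathway activation
  u_prot <- matrix(0, G, 3)
  if (n_inf > 0)
    u_prot[i_inf, ] <- matrix(stats::rnorm(n_inf * 3, 0, s$subgroup_shift),
                              n_inf, 3)

  ## pathways: the last quarter draw from the planted-correlation genes
  ## (the KS enrichment stage should find them); the rest, including the
  ## active ones, draw from the other genes so pathway activation never
  ## perturbs the correlation calibration
  pool <- setdiff(seq_len(G), i_corr)
  path_names <- sprintf("METABOLIC_PATHWAY_%02d", seq_len(s$n_pathways))
  n_corr_paths <- if (n_corr >= 5) max(1, round(s$n_pathways / 4)) else 0
  path_genes <- lapply(seq_len(s$n_pathways), function(p) {
    src <- if (p > s$n_pathways - n_corr_paths) i_corr else pool
    genes[sort(sample(src, min(s$pathway_size, length(src))))]
  })
  names(path_genes) <- path_names
  pathways <- pathway_db(path_genes,
                         stats::setNames(rep("metabolic", s$n_pathways),
                                         path_names))
  n_act <- s$n_active_pathways_per_subgroup
  active <- lapply(1:3, function(c) path_names[(c - 1) * n_act + seq_len(n_act)])
  names(active) <- as.character(1:3)
  act_shift <- log2(s$pathway_activation)
  for (c in 1:3) {
    g_act <- match(unique(unlist(path_genes[active[[c]]])), genes)
    u_prot[g_act, c] <- u_prot[g_act, c] + act_shift
  }

  # planted mRNA-protein correlation: Spearman target -> Pearson target for
  # the bivariate-normal pair, then the signal weight w
  rho_p <- 2 * sin(pi * s$target_rho_pos / 6)
  f_sd <- s$sd_protein_noise
  protein <- b + u_prot[, subgroup] +
    matrix(stats::rnorm(G * n, 0, f_sd), G, n)
  if (n_corr > 0) {
    if (f_sd == 0 || rho_p >= 0.999) {
      protein[i_corr, ] <- b[i_corr] + e[i_corr, , drop = FALSE]
    } else {
      w <- rho_p * f_sd / (s$sd_mrna_noise * sqrt(1 - rho_p^2))
      protein[i_corr, ] <- protein[i_corr, , drop = FALSE] +
        w * e[i_corr, , drop = FALSE]
    }
  }
  # MI/MA marker genes: protein shift in MI samples
  if (length(i_mark) > 0) {
    mi <- !is.na(phenotype) & phenotype == "MI"
    protein[i_mark, mi] <- protein[i_mark, mi] + s$marker_effect
  }
  dimnames(protein) <- list(genes, samples)
  dimnames(mrna) <- list(genes, samples)

  ## --- protein missingness: MCAR + low-abundance dropout ------------------
  mcar <- matrix(stats::runif(G * n) < s$missing_rate_protein, G, n)
  low <- protein <= stats::quantile(protein, 0.1)
  extra <- matrix(stats::runif(G * n) < s$low_abundance_extra, G, n) & low
  protein[mcar | extra] <- NA_real_

  ## --- signatures GMT ------------------------------------------------------
  sig_names <- c("TCELL", "BCELL", "NKCELL", "MACROPHAGE",
                 "FIBROBLAST", "ENDOTHELIAL", "HEPATOCYTE", "CHOLANGIOCYTE")
  sig_desc <- c(rep("immune", 4), rep("stromal", 2), rep("parenchymal", 2))
  sig_genes <- split(genes[i_sig], rep(seq_len(8), each = s$signature_size))
  names(sig_genes) <- paste0("CELLTYPE_", sig_names)
  signatures <- pathway_db(sig_genes,
                           stats::setNames(sig_desc, names(sig_genes)))

  truth <- list(
    subgroup_of_sample = subgroup,
    positively_correlated_genes = genes[i_corr],
    attenuated_genes = genes[i_att],
    active_pathways_by_subgroup = active,
    informative_genes = genes[i_inf],
    marker_genes = genes[i_mark],
    correlated_pathways =
      if (n_corr_paths > 0)
        path_names[seq(s$n_pathways - n_corr_paths + 1, s$n_pathways)]
      else character(0),
    immune_hot_subgroup = s$immune_hot_subgroup,
    dmr_regions = regions$region_id[sort(unique(dmr_rows))])

  structure(list(
    protein = omics_matrix(protein, "log-abundance"),
    mrna = omics_matrix(mrna, "log-abundance"),
    methylation = omics_matrix(beta, "beta"),
    regions = regions, gene_model = gene_model, clinical = clinical,
    pathways = pathways, signatures = signatures,
    truth = truth, spec = s), class = "synthetic_cohort")
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat(sprintf(paste0("synthetic_cohort: %d samples, %d genes, %d regions, ",
                     "%d pathways (seed %d)\n"),
              x$spec$n_samples, x$spec$n_genes, nrow(x$regions),
              length(x$pathways$genes), x$spec$seed))
  invisible(x)
}

#' Write a synthetic cohort to a directory
#'
#' Emits the pipeline's external formats (TSV matrices, BED-like region
#' table, gene model table, GMT pathway/signature files, clinical CSV) plus
#' ground-truth tables, and returns a manifest with per-file MD5 checksums.
#'
#' @param cohort A [simulate_cohort()] result.
#' @param dir Output directory (created if needed).
#' @return data.frame manifest (`file`, `role`, `md5`), invisibly also
#'   written to `manifest.tsv`.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "synthetic_cohort"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  p <- function(f) file.path(dir, f)
  write_matrix(cohort$protein, p("protein.tsv"), "gene")
  write_matrix(cohort$mrna, p("mrna.tsv"), "gene")
  write_matrix(cohort$methylation, p("methylation.tsv"), "region_id")
  write_regions(cohort$regions, p("regions.tsv"))
  write_gene_model(cohort$gene_model, p("gene_model.tsv"))
  write_clinical(cohort$clinical, p("clinical.csv"))
  write_gmt(cohort$pathways, p("pathways.gmt"))
  write_gmt(cohort$signatures, p("signatures.gmt"))
  tr <- cohort$truth
  utils::write.table(
    data.frame(sample = names(tr$subgroup_of_sample),
               subgroup = unname(tr$subgroup_of_sample)),
    p("truth_subgroups.tsv"), sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(
    data.frame(gene = rownames(cohort$protein),
               positively_correlated =
                 as.integer(rownames(cohort$protein) %in%
                              tr$positively_correlated_genes),
               attenuated = as.integer(rownames(cohort$protein) %in%
                                         tr$attenuated_genes),
               marker = as.integer(rownames(cohort$protein) %in%
                                     tr$marker_genes)),
    p("truth_genes.tsv"), sep = "\t", quote = FALSE, row.names = FALSE)
  files <- c(protein = "protein.tsv", mrna = "mrna.tsv",
             methylation = "methylation.tsv", regions = "regions.tsv",
             gene_model = "gene_model.tsv", clinical = "clinical.csv",
             pathways = "pathways.gmt", signatures = "signatures.gmt",
             truth_subgroups = "truth_subgroups.tsv",
             truth_genes = "truth_genes.tsv")
  manifest <- data.frame(file = unname(files), role = names(files),
                         md5 = unname(tools::md5sum(file.path(dir, files))),
                         stringsAsFactors = FALSE)
  utils::write.table(manifest, p("manifest.tsv"), sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(manifest)
}
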