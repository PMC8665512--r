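# End-to-end orchestration: read (or accept) all inputs, run every stage in
# dependency order with per-stage seeds derived from one global seed, log
# input/output counts, and write the report tables.

default_pipeline_params <- function() {
  list(
    preprocess = list(max_missing_fraction = 0.5, impute_method = "half_min",
                      knn_k = 5, variance_fraction = 0.25,
                      variance_metric = "mad"),
    correlation = list(method = "spearman", alpha = 0.01, min_members = 5),
    clustering = list(k_range = 2:6, n_resamples = 1000,
                      subsample_fraction = 0.8, fixed_k = NULL),
    de = list(alpha = 0.05),
    pas = list(B = 999, alpha = 0.05),
    methylation = list(alpha = 0.05, min_delta = 0.1, promoter_window = 1500,
                       posterior_cutoff = 0.5),
    survival = list(horizon_months = 24,
                    covariates = c("tnm_stage", "afp_high", "thrombus"))
  )
}

merge_params <- function(base, user) {
  for (nm in names(user)) {
    if (is.list(base[[nm]]) && is.list(user[[nm]]))
      base[[nm]] <- utils::modifyList(base[[nm]], user[[nm]])
    else base[[nm]] <- user[[nm]]
  }
  base
}

read_pipeline_inputs <- function(inputs, verbose = TRUE) {
  get_in <- function(key, reader, required = FALSE) {
    val <- inputs[[key]]
    if (is.null(val)) {
      if (required) stop("run_pipeline: required input '", key, "' missing")
      return(NULL)
    }
    if (is.character(val)) {
      if (!file.exists(val))
        stop("run_pipeline: input file for '", key, "' not found: ", val)
      reader(val)
    } else val
  }
  list(
    protein = get_in("protein", function(p) read_matrix(p, "log-abundance"),
                     required = TRUE),
    mrna = get_in("mrna", function(p) read_matrix(p, "log-abundance"),
                  required = TRUE),
    methylation = get_in("methylation", function(p) read_matrix(p, "beta")),
    regions = get_in("regions", read_regions),
    gene_model = get_in("gene_model", read_gene_model),
    clinical = get_in("clinical", read_clinical, required = TRUE),
    pathways = get_in("pathways", read_gmt, required = TRUE),
    signatures = get_in("signatures", read_gmt))
}

#' Run the full proteogenomic pipeline
#'
#' Stages run in dependency order: preprocessing (missingness filter,
#' imputation, variable-feature selection), mRNA-protein correlation with
#' KS pathway enrichment, consensus subgroup discovery with KW
#' differential expression and clinical association, pathway activity
#' scores, the methylation stage (DMRs, annotation, attenuation mixture,
#' ORA) when methylation inputs are present (skipped with a logged reason
#' otherwise), survival analyses, signature scores, and the cross-omics
#' overlap table. One global seed fans out to per-stage seeds by fixed
#' offsets so single stages are individually reproducible.
#'
#' @param config Named list (or path to a YAML file) with elements
#'   `inputs` (paths or in-memory objects: protein, mrna, clinical,
#'   pathways required; methylation, regions, gene_model, signatures
#'   optional), `seed`, optional `output_dir`, and optional per-stage
#'   parameter overrides (`preprocess`, `correlation`, `clustering`, `de`,
#'   `pas`, `methylation`, `survival`).
#' @param verbose Log stage counts to stderr.
#' @return List of class `pipeline_report` with every stage's tables and a
#'   `summary` data.frame of counts; tables are also written as TSV when
#'   `output_dir` is set.
#' @export
run_pipeline <- function(config, verbose = TRUE) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  stopifnot(is.list(config))
  seed <- config$seed
  if (is.null(seed)) stop("run_pipeline: config$seed is required")
  params <- merge_params(default_pipeline_params(),
                         config[names(config) %in%
                                  names(default_pipeline_params())])
  params$clustering$k_range <- as.integer(unlist(params$clustering$k_range))
  if (length(params$clustering$k_range) == 2 &&
      diff(params$clustering$k_range) > 1)
    params$clustering$k_range <-
      params$clustering$k_range[1]:params$clustering$k_range[2]
  inp <- read_pipeline_inputs(config$inputs, verbose)
  counts <- list()
  note <- function(stage, what, n) {
    counts[[length(counts) + 1]] <<- data.frame(
      stage = stage, quantity = what, n = n, stringsAsFactors = FALSE)
    pipe_log(stage, ": ", what, " = ", n, verbose = verbose)
  }

  ## 1. preprocess protein
  note("input", "proteins identified", nrow(inp$protein))
  note("input", "samples", ncol(inp$protein))
  filt <- filter_missing(inp$protein, params$preprocess$max_missing_fraction)
  note("preprocess", "proteins after missingness filter", nrow(filt))
  imp <- impute_missing(filt, params$preprocess$impute_method,
                        params$preprocess$knn_k)
  varm <- select_variable(imp, params$preprocess$variance_fraction,
                          params$preprocess$variance_metric)
  note("preprocess", "high-variance proteins", nrow(varm))

  ## 2. mRNA-protein correlation + enrichment
  paired <- pair_genes(imp, inp$mrna)
  note("correlation", "mRNA-protein pairs", paired$n_pairs)
  note("correlation", "paired samples", paired$n_samples)
  corr <- correlate_expression(paired, params$correlation$method,
                               params$correlation$alpha)
  note("correlation", "significant positive pairs", corr$summary$n_sig_pos)
  rho <- stats::setNames(corr$records$rho, corr$records$gene)
  rho <- rho[!corr$records$flagged]
  enrich <- ks_pathway_enrichment(rho, inp$pathways,
                                  params$correlation$min_members)

  ## 3. subgroup discovery
  cl_assign <- consensus_cluster(
    varm, params$clustering$k_range, params$clustering$n_resamples,
    params$clustering$subsample_fraction, seed = seed + 1,
    fixed_k = params$clustering$fixed_k)
  note("clustering", "selected K", cl_assign$k)
  labels <- cl_assign$labels
  de <- kw_differential(varm, labels, params$de$alpha)
  note("de", "DE proteins among subgroups", sum(de$significant))
  assoc <- clinical_association(labels, inp$clinical)

  ## thrombus two-group DE on the full imputed matrix
  thr <- inp$clinical$thrombus[match(colnames(imp), inp$clinical$sample)]
  de_thrombus <- NULL
  if (length(unique(stats::na.omit(thr))) == 2 && all(table(thr) >= 2)) {
    ok <- !is.na(thr)
    de_thrombus <- kw_differential(
      imp[, ok], stats::setNames(thr[ok], colnames(imp)[ok]), params$de$alpha)
    note("de", "DE proteins by tumor thrombus", sum(de_thrombus$significant))
  } else {
    pipe_log("thrombus DE skipped: fewer than 2 usable thrombus groups",
             verbose = verbose)
  }

  ## 4. pathway activity
  pas <- pathway_activity_score(imp, labels, inp$pathways,
                                B = params$pas$B, alpha = params$pas$alpha,
                                seed = seed + 2, input_scale = "log2")
  note("pas", "significant pathway-subgroup activities", sum(pas$significant))
  pas_matrix <- pas_heatmap_table(pas, params$pas$alpha)

  ## 5. methylation branch (optional)
  meth_res <- NULL
  if (!is.null(inp$methylation) && !is.null(inp$regions) &&
      !is.null(inp$gene_model)) {
    dmrs <- call_dmrs(inp$methylation, inp$regions, labels,
                      params$methylation$alpha, params$methylation$min_delta,
                      verbose = verbose)
    note("methylation", "DMRs detected", sum(dmrs$dmr))
    ann <- annotate_regions(inp$regions, inp$gene_model,
                            params$methylation$promoter_window)
    dmr_ann <- merge(dmrs[dmrs$dmr, c("region_id", "adj_p",
                                      "max_delta_beta")],
                     ann[, c("region_id", "annotation", "linked_gene")],
                     by = "region_id")
    links <- dmr_ann[dmr_ann$annotation %in% c("promoter", "gene_body"), ,
                     drop = FALSE]
    atten <- tryCatch(
      attenuation_gmm(inp$methylation, inp$mrna, imp, links,
                      params$methylation$posterior_cutoff, seed = seed + 3),
      error = function(e) {
        pipe_log("attenuation skipped: ", conditionMessage(e),
                 verbose = verbose)
        NULL
      })
    ora <- NULL
    if (!is.null(atten)) {
      note("methylation", "genes analyzed for attenuation",
           atten$summary$n_analyzed)
      note("methylation", "attenuated proteins", atten$summary$n_attenuated)
      if (atten$summary$n_attenuated > 0)
        ora <- hypergeom_ora(atten$records$gene[atten$records$attenuated],
                             atten$records$gene, inp$pathways)
    }
    meth_res <- list(dmrs = dmrs, annotated = dmr_ann, attenuation = atten,
                     ora = ora)
  } else {
    pipe_log("methylation stage skipped: inputs absent", verbose = verbose)
  }

  ## 6. survival
  flags <- early_relapse_flag(inp$clinical, params$survival$horizon_months)
  flags <- flags[names(labels)]
  names(flags) <- names(labels)
  prop <- relapse_proportion_test(flags, labels)
  tnm <- stats::setNames(inp$clinical$tnm_stage, inp$clinical$sample)
  prop_strat <- relapse_proportion_test(flags, labels,
                                        strata = tnm[names(labels)])
  km <- tryCatch(km_logrank(inp$clinical, labels,
                            params$survival$horizon_months),
                 error = function(e) {
                   pipe_log("KM skipped: ", conditionMessage(e),
                            verbose = verbose); NULL
                 })
  cox <- tryCatch(cox_multivariable(inp$clinical, labels,
                                    params$survival$covariates,
                                    params$survival$horizon_months),
                  error = function(e) {
                    pipe_log("Cox skipped: ", conditionMessage(e),
                             verbose = verbose); NULL
                  })
  markers <- tryCatch(marker_screen(imp, inp$clinical,
                                    covariates = params$survival$covariates),
                      error = function(e) {
                        pipe_log("marker screen skipped: ",
                                 conditionMessage(e), verbose = verbose)
                        NULL
                      })
  if (!is.null(markers)) note("survival", "markers passing all stages",
                              sum(markers$passed))

  ## 7. signature scores
  sig_scores <- NULL
  if (!is.null(inp$signatures)) {
    sig_scores <- tryCatch(signature_scores(inp$mrna, inp$signatures),
                           error = function(e) {
                             pipe_log("signature scores skipped: ",
                                      conditionMessage(e), verbose = verbose)
                             NULL
                           })
  }

  ## 8. cross-omics overlap
  sets <- list(
    positive_correlation = corr$records$gene[
      !corr$records$flagged & corr$records$adj_p < params$correlation$alpha &
        corr$records$rho > 0],
    de_protein = de$feature[de$significant])
  if (!is.null(meth_res) && !is.null(meth_res$attenuation))
    sets$attenuated <- meth_res$attenuation$records$gene[
      meth_res$attenuation$records$attenuated]
  overlap <- overlap_summary(sets)

  report <- structure(list(
    params = params, seed = seed,
    preprocess = list(n_input = nrow(inp$protein), n_filtered = nrow(filt),
                      n_variable = nrow(varm)),
    imputed = imp, variable_matrix = varm,
    correlation = corr, enrichment = enrich,
    clustering = cl_assign, de = de, de_thrombus = de_thrombus,
    clinical_association = assoc,
    pas = pas, pas_matrix = pas_matrix,
    methylation = meth_res,
    survival = list(early_relapse = flags, proportion = prop,
                    proportion_stratified = prop_strat, km = km, cox = cox,
                    markers = markers),
    signature_scores = sig_scores,
    overlap = overlap,
    summary = do.call(rbind, c(counts, make.row.names = FALSE))),
    class = "pipeline_report")

  if (!is.null(config$output_dir))
    write_report(report, config$output_dir)
  report
}

#' @export
print.pipeline_report <- function(x, ...) {
  cat("pipeline_report\n")
  print(x$summary, row.names = FALSE)
  invisible(x)
}

#' Write the report tables of a pipeline run
#'
#' Emits every stage's table as TSV under `dir` with deterministic
#' formatting, so identical config + seed give byte-identical files.
#'
#' @param report A [run_pipeline()] result.
#' @param dir Output directory.
#' @return Character vector of written paths, invisibly.
#' @export
write_report <- function(report, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  written <- character(0)
  wt <- function(df, name) {
    path <- file.path(dir, name)
    utils::write.table(df, path, sep = "\t", quote = FALSE,
                       row.names = FALSE, na = "NA")
    written <<- c(written, path)
  }
  wt(report$summary, "summary.tsv")
  wt(report$correlation$records, "correlation_records.tsv")
  wt(report$enrichment, "ks_enrichment.tsv")
  wt(data.frame(sample = names(report$clustering$labels),
                subgroup = unname(report$clustering$labels)),
     "subgroup_labels.tsv")
  wt(report$clustering$selection_trace, "cluster_selection.tsv")
  cons <- report$clustering$consensus
  wt(data.frame(sample = rownames(cons), cons, check.names = FALSE),
     "consensus_matrix.tsv")
  wt(report$de, "de_subgroups.tsv")
  if (!is.null(report$de_thrombus)) wt(report$de_thrombus, "de_thrombus.tsv")
  wt(report$clinical_association, "clinical_association.tsv")
  wt(as.data.frame(report$pas), "pas_long.tsv")
  pm <- report$pas_matrix
  wt(data.frame(pathway = rownames(pm), pm, check.names = FALSE),
     "pas_matrix.tsv")
  if (!is.null(report$methylation)) {
    wt(report$methylation$dmrs, "dmrs.tsv")
    wt(report$methylation$annotated, "dmrs_annotated.tsv")
    if (!is.null(report$methylation$attenuation))
      wt(report$methylation$attenuation$records, "attenuation.tsv")
    if (!is.null(report$methylation$ora))
      wt(report$methylation$ora, "attenuated_ora.tsv")
  }
  sv <- report$survival
  wt(data.frame(sample = names(sv$early_relapse),
                early_relapse = unname(sv$early_relapse)),
     "early_relapse.tsv")
  wt(sv$proportion, "relapse_proportion.tsv")
  wt(sv$proportion_stratified, "relapse_proportion_stratified.tsv")
  if (!is.null(sv$km)) wt(sv$km$curves, "km_curves.tsv")
  if (!is.null(sv$cox)) wt(sv$cox$coefficients, "cox_coefficients.tsv")
  if (!is.null(sv$markers)) wt(sv$markers, "marker_screen.tsv")
  if (!is.null(report$signature_scores))
    wt(report$signature_scores, "signature_scores.tsv")
  wt(report$overlap, "overlap_summary.tsv")
  invisible(written)
}
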