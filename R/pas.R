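# Pathway activity scores per subgroup with a label-permutation null.

#' Pathway activity scores with a permutation test
#'
#' On the linear scale, the relative abundance of gene g in sample i is its
#' value divided by the gene's mean over all samples. The activity of
#' pathway j in subgroup c is the mean relative abundance of the pathway's
#' genes over the subgroup's samples; 1 means cohort-average activity.
#' Significance comes from `B` random permutations of the subgroup labels,
#' two-sided around 1: `perm_p = (1 + #{|PAS_perm - 1| >= |PAS_obs - 1|}) /
#' (B + 1)`. Permuting sample labels preserves the gene-gene covariance.
#'
#' Log2 input is exponentiated first (ratios of log values are not
#' meaningful); linear input must be non-negative.
#'
#' @param m An [omics_matrix()] with no missing values.
#' @param labels Named subgroup labels covering the columns of `m`; every
#'   subgroup needs at least 3 samples.
#' @param pathways A [pathway_db()].
#' @param B Number of permutations (default 999).
#' @param alpha Significance level (default 0.05).
#' @param seed Integer seed for the permutations.
#' @param input_scale `"log2"` (default; exponentiated) or `"linear"`.
#' @return data.frame of class `pas_result`: pathway, subgroup, n_genes,
#'   pas, perm_p, significant. Pathways with no measured gene are skipped
#'   (listed in the `skipped` attribute).
#' @export
pathway_activity_score <- function(m, labels, pathways, B = 999,
                                   alpha = 0.05, seed = 1,
                                   input_scale = c("log2", "linear")) {
  input_scale <- match.arg(input_scale)
  stopifnot(inherits(m, "omics_matrix"), inherits(pathways, "pathway_db"),
            B >= 1)
  if (anyNA(m)) stop("pathway_activity_score: matrix must have no missing values")
  labels <- labels[colnames(m)]
  if (anyNA(labels)) stop("pathway_activity_score: labels missing for samples")
  g <- factor(labels)
  sizes <- table(g)
  if (any(sizes < 3)) stop("pathway_activity_score: subgroup with < 3 samples")
  x <- unclass(m)
  if (input_scale == "log2") x <- 2^x
  if (any(x < 0)) stop("pathway_activity_score: linear abundances must be >= 0")
  rm_ <- rowMeans(x)
  if (any(rm_ == 0)) stop("pathway_activity_score: gene with all-zero abundance")
  rel <- x / rm_

  keep <- lapply(pathways$genes, intersect, rownames(rel))
  skipped <- names(keep)[lengths(keep) == 0]
  keep <- keep[lengths(keep) > 0]
  if (length(keep) == 0) stop("pathway_activity_score: no pathway has measured genes")

  # pathway x gene membership matrix (rows average member genes)
  M <- matrix(0, length(keep), nrow(rel),
              dimnames = list(names(keep), rownames(rel)))
  for (j in seq_along(keep)) M[j, keep[[j]]] <- 1 / length(keep[[j]])

  grp_means <- function(lab) {
    # gene x subgroup matrix of within-subgroup mean relative abundance
    ind <- stats::model.matrix(~ lab - 1)
    sweep(rel %*% ind, 2, colSums(ind), "/")
  }
  obs <- M %*% grp_means(g)                       # pathways x subgroups
  colnames(obs) <- levels(g)
  dev_obs <- abs(obs - 1)

  exceed <- matrix(0, nrow(obs), ncol(obs))
  with_rng_seed(seed, {
    for (b in seq_len(B)) {
      perm <- M %*% grp_means(sample(g))
      exceed <- exceed + (abs(perm - 1) >= dev_obs)
    }
  })
  perm_p <- (1 + exceed) / (B + 1)

  out <- data.frame(
    pathway = rep(rownames(obs), times = ncol(obs)),
    subgroup = rep(colnames(obs), each = nrow(obs)),
    n_genes = rep(lengths(keep), times = ncol(obs)),
    pas = as.vector(obs),
    perm_p = as.vector(perm_p),
    stringsAsFactors = FALSE)
  out$significant <- out$perm_p <= alpha
  attr(out, "skipped") <- skipped
  attr(out, "subgroup_sizes") <- as.vector(sizes)
  class(out) <- c("pas_result", "data.frame")
  out
}

#' Pathway x subgroup activity matrix with non-significant cells masked
#'
#' Reshapes a [pathway_activity_score()] result into a matrix and masks
#' (sets to `NA`) exactly the cells with `perm_p > alpha` — the blank cells
#' of the activity heatmap. Masking is idempotent.
#'
#' @param results A `pas_result` data.frame.
#' @param alpha Significance level (default 0.05).
#' @return Numeric matrix pathway x subgroup with `NA` in masked cells.
#' @export
pas_heatmap_table <- function(results, alpha = 0.05) {
  stopifnot(is.data.frame(results),
            all(c("pathway", "subgroup", "pas", "perm_p") %in% names(results)))
  paths <- unique(results$pathway)
  grps <- unique(results$subgroup)
  mat <- matrix(NA_real_, length(paths), length(grps),
                dimnames = list(paths, grps))
  keep <- results$perm_p <= alpha
  mat[cbind(match(results$pathway[keep], paths),
            match(results$subgroup[keep], grps))] <- results$pas[keep]
  mat
}
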