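# Core containers: omics_matrix (feature x sample with missingness),
# pathway_db (named gene sets), clinical table validation.

#' Construct an omics matrix
#'
#' The common currency of the pipeline: a numeric feature x sample matrix
#' with unique row (feature) and column (sample) names. Missing entries are
#' encoded as `NA`; the missingness mask is therefore `is.na(x)`. Matrices
#' in the `"beta"` domain (methylation fractions) must lie in `[0, 1]`
#' where observed.
#'
#' @param values Numeric matrix with rownames (feature IDs) and colnames
#'   (sample IDs).
#' @param value_domain `"log-abundance"` (default) or `"beta"`.
#' @return An object of class `omics_matrix` (a classed numeric matrix with
#'   a `value_domain` attribute).
#' @export
omics_matrix <- function(values, value_domain = c("log-abundance", "beta")) {
  value_domain <- match.arg(value_domain)
  if (!is.matrix(values) || !is.numeric(values)) {
    stop("omics_matrix: 'values' must be a numeric matrix")
  }
  fid <- rownames(values)
  sid <- colnames(values)
  if (is.null(fid) || is.null(sid)) {
    stop("omics_matrix: row (feature) and column (sample) names are required")
  }
  if (anyDuplicated(fid)) {
    stop("omics_matrix: duplicate feature IDs: ",
         paste(unique(fid[duplicated(fid)]), collapse = ", "))
  }
  if (anyDuplicated(sid)) {
    stop("omics_matrix: duplicate sample IDs: ",
         paste(unique(sid[duplicated(sid)]), collapse = ", "))
  }
  if (value_domain == "beta") {
    obs <- !is.na(values)
    bad <- obs & (values < 0 | values > 1)
    if (any(bad)) {
      idx <- which(bad, arr.ind = TRUE)[1, ]
      stop(sprintf(
        "omics_matrix: beta value out of [0,1] at feature '%s', sample '%s' (%g)",
        fid[idx[1]], sid[idx[2]], values[idx[1], idx[2]]))
    }
  }
  structure(values, value_domain = value_domain,
            class = c("omics_matrix", class(values)))
}

#' @export
`[.omics_matrix` <- function(x, i, j, ..., drop = FALSE) {
  vd <- attr(x, "value_domain")
  y <- unclass(x)
  y <- if (missing(i) && missing(j)) y
       else if (missing(i)) y[, j, drop = drop]
       else if (missing(j)) y[i, , drop = drop]
       else y[i, j, drop = drop]
  if (is.matrix(y)) omics_matrix(y, vd) else y
}

#' @export
print.omics_matrix <- function(x, ...) {
  cat(sprintf("omics_matrix [%s]: %d features x %d samples, %.1f%% missing\n",
              attr(x, "value_domain"), nrow(x), ncol(x),
              100 * mean(is.na(x))))
  invisible(x)
}

#' Missingness mask of an omics matrix
#' @param m An `omics_matrix`.
#' @return Logical matrix, `TRUE` where the entry is missing.
#' @export
missing_mask <- function(m) is.na(unclass(m))

#' Construct a pathway database
#'
#' Named gene sets with a free-text description per set (the description
#' field carries category tags such as `"immune"`/`"stromal"` for
#' microenvironment signatures).
#'
#' @param genesets Named list of character vectors (non-empty, unique names).
#' @param descriptions Optional named character vector; defaults to `""`.
#' @return Object of class `pathway_db`: list with elements `genes`
#'   (named list) and `description` (named character).
#' @export
pathway_db <- function(genesets, descriptions = NULL) {
  if (length(genesets) > 0 &&
      (is.null(names(genesets)) || any(names(genesets) == "")))
    stop("pathway_db: all gene sets must be named")
  if (anyDuplicated(names(genesets)))
    stop("pathway_db: duplicate pathway names")
  genesets <- lapply(genesets, function(g) unique(as.character(g)))
  if (any(lengths(genesets) == 0))
    stop("pathway_db: empty gene set(s): ",
         paste(names(genesets)[lengths(genesets) == 0], collapse = ", "))
  if (is.null(descriptions)) {
    descriptions <- stats::setNames(rep("", length(genesets)), names(genesets))
  } else {
    descriptions <- stats::setNames(
      as.character(descriptions[names(genesets)]), names(genesets))
    descriptions[is.na(descriptions)] <- ""
  }
  structure(list(genes = genesets, description = descriptions),
            class = "pathway_db")
}

#' @export
print.pathway_db <- function(x, ...) {
  cat(sprintf("pathway_db: %d gene sets (sizes %s)\n", length(x$genes),
              if (length(x$genes)) paste(range(lengths(x$genes)), collapse = "-")
              else "-"))
  invisible(x)
}

#' @export
length.pathway_db <- function(x) length(x$genes)

# Clinical table schema shared by read_clinical() and the simulator.
clinical_columns <- c("sample", "rfs_months", "rfs_event", "tnm_stage",
                      "afp_high", "thrombus", "phenotype")

#' Validate a clinical table
#'
#' Checks the per-sample outcome/covariate table used by the survival and
#' association stages: one row per sample; `rfs_months >= 0`;
#' `rfs_event` in {0,1}; `tnm_stage` in I-IV; `afp_high`/`thrombus` binary;
#' `phenotype` in {MI, MA, NA}.
#'
#' @param clinical A data.frame.
#' @return The validated data.frame (invisibly unchanged).
#' @export
validate_clinical <- function(clinical) {
  if (!is.data.frame(clinical)) stop("clinical table must be a data.frame")
  miss <- setdiff(clinical_columns, names(clinical))
  if (length(miss)) stop("clinical table missing column(s): ",
                         paste(miss, collapse = ", "))
  if (anyDuplicated(clinical$sample))
    stop("clinical table: duplicate sample ID(s): ",
         paste(unique(clinical$sample[duplicated(clinical$sample)]),
               collapse = ", "))
  if (any(!is.finite(clinical$rfs_months)) || any(clinical$rfs_months < 0))
    stop("clinical table: rfs_months must be finite and >= 0")
  if (!all(clinical$rfs_event %in% c(0, 1)))
    stop("clinical table: rfs_event must be 0 or 1")
  tnm_to_int(clinical$tnm_stage)  # errors on unknown stage strings
  for (v in c("afp_high", "thrombus")) {
    x <- clinical[[v]]
    if (!all(is.na(x) | x %in% c(0, 1)))
      stop("clinical table: ", v, " must be 0, 1 or NA")
  }
  ph <- clinical$phenotype
  if (!all(is.na(ph) | ph %in% c("MI", "MA")))
    stop("clinical table: phenotype must be MI, MA or NA")
  invisible(clinical)
}
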