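# Readers/writers for the plain-text formats the pipeline exchanges:
# TSV matrices, GMT gene sets, clinical CSV, BED-like region tables and a
# gene model table. Readers validate and reject rather than coerce.

#' Read a feature x sample matrix from TSV
#'
#' First column = feature ID, header = sample IDs, missing entries written
#' as `NA`. Beta-domain matrices are bound-checked on read.
#'
#' @param path File path.
#' @param value_domain `"log-abundance"` or `"beta"`.
#' @return An [omics_matrix()].
#' @export
read_matrix <- function(path, value_domain = c("log-abundance", "beta")) {
  value_domain <- match.arg(value_domain)
  df <- utils::read.delim(path, header = TRUE, sep = "\t", check.names = FALSE,
                          colClasses = "character", na.strings = NULL)
  if (ncol(df) < 2) stop("read_matrix: expected feature column plus >=1 sample")
  fid <- df[[1]]
  if (anyDuplicated(fid))
    stop("read_matrix: duplicate feature ID(s): ",
         paste(unique(fid[duplicated(fid)]), collapse = ", "))
  raw <- as.matrix(df[, -1, drop = FALSE])
  vals <- suppressWarnings(array(as.numeric(raw), dim = dim(raw)))
  bad_token <- raw != "NA" & is.na(vals)
  if (any(bad_token)) {
    idx <- which(bad_token, arr.ind = TRUE)[1, ]
    stop(sprintf("read_matrix: non-numeric token '%s' at feature '%s', sample '%s'",
                 raw[idx[1], idx[2]], fid[idx[1]], colnames(raw)[idx[2]]))
  }
  vals[raw == "NA"] <- NA_real_
  dimnames(vals) <- list(fid, colnames(df)[-1])
  omics_matrix(vals, value_domain)
}

#' Write a feature x sample matrix to TSV
#'
#' @param m An [omics_matrix()].
#' @param path Output path.
#' @param feature_col Name of the first (feature ID) column.
#' @return `path`, invisibly.
#' @export
write_matrix <- function(m, path, feature_col = "feature") {
  df <- data.frame(rownames(m), unclass(m), check.names = FALSE,
                   stringsAsFactors = FALSE)
  names(df) <- c(feature_col, colnames(m))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "NA")
  invisible(path)
}

#' Read gene sets from a GMT file
#'
#' Standard GMT: one set per line, tab-separated `name`, `description`,
#' then gene symbols. Lines with zero genes are rejected.
#'
#' @param path File path.
#' @return A [pathway_db()].
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0) return(pathway_db(list()))
  fields <- strsplit(lines, "\t", fixed = TRUE)
  short <- which(lengths(fields) < 3)
  if (length(short))
    stop("read_gmt: line(s) with no genes: ",
         paste(utils::head(short, 5), collapse = ", "))
  nm <- vapply(fields, `[[`, "", 1)
  desc <- vapply(fields, `[[`, "", 2)
  genes <- lapply(fields, function(f) f[-(1:2)][nzchar(f[-(1:2)])])
  if (any(lengths(genes) == 0))
    stop("read_gmt: line(s) with no genes: ",
         paste(which(lengths(genes) == 0), collapse = ", "))
  pathway_db(stats::setNames(genes, nm), stats::setNames(desc, nm))
}

#' Write gene sets to a GMT file
#' @param db A [pathway_db()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gmt <- function(db, path) {
  stopifnot(inherits(db, "pathway_db"))
  lines <- vapply(names(db$genes), function(nm) {
    paste(c(nm, db$description[[nm]], db$genes[[nm]]), collapse = "\t")
  }, "")
  writeLines(lines, path)
  invisible(path)
}

#' Read the clinical table from CSV
#'
#' Columns: `sample, rfs_months, rfs_event, tnm_stage, afp_high, thrombus,
#' phenotype`. Validated with [validate_clinical()]; empty `phenotype`
#' fields and the literal `NA` are treated as missing.
#'
#' @param path File path.
#' @return A validated data.frame.
#' @export
read_clinical <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        na.strings = c("NA", ""))
  df$sample <- as.character(df$sample)
  df$tnm_stage <- as.character(df$tnm_stage)
  df$phenotype <- if ("phenotype" %in% names(df))
    as.character(df$phenotype) else NA_character_
  validate_clinical(df)
  df
}

#' Write the clinical table to CSV
#' @param clinical Validated clinical data.frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_clinical <- function(clinical, path) {
  validate_clinical(clinical)
  utils::write.csv(clinical[, clinical_columns], path, row.names = FALSE,
                   quote = FALSE, na = "NA")
  invisible(path)
}

# --- BED-like regions and gene model tables (0-based half-open) ---------------

region_columns <- c("chrom", "start", "end", "region_id", "linked_gene")
gene_model_columns <- c("gene", "chrom", "tss", "strand",
                        "gene_start", "gene_end")

#' Read a BED-like methylation region table
#'
#' Tab-separated with header: `chrom, start, end, region_id, linked_gene`
#' (0-based half-open coordinates; `linked_gene` may be `NA`).
#'
#' @param path File path.
#' @return data.frame of regions.
#' @export
read_regions <- function(path) {
  df <- utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE,
                          na.strings = c("NA", ""))
  miss <- setdiff(region_columns, names(df))
  if (length(miss)) stop("read_regions: missing column(s): ",
                         paste(miss, collapse = ", "))
  if (anyDuplicated(df$region_id)) stop("read_regions: duplicate region_id")
  if (any(!is.finite(df$start)) || any(!is.finite(df$end)) ||
      any(df$start < 0) || any(df$start >= df$end))
    stop("read_regions: malformed coordinates (need 0 <= start < end)")
  df
}

#' @rdname read_regions
#' @param regions data.frame of regions.
#' @export
write_regions <- function(regions, path) {
  utils::write.table(regions[, region_columns], path, sep = "\t",
                     quote = FALSE, row.names = FALSE, na = "NA")
  invisible(path)
}

#' Read a gene model table
#'
#' Tab-separated with header: `gene, chrom, tss, strand, gene_start,
#' gene_end` (0-based; strand `+`/`-`).
#'
#' @param path File path.
#' @return data.frame of gene models.
#' @export
read_gene_model <- function(path) {
  df <- utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE)
  miss <- setdiff(gene_model_columns, names(df))
  if (length(miss)) stop("read_gene_model: missing column(s): ",
                         paste(miss, collapse = ", "))
  if (anyDuplicated(df$gene)) stop("read_gene_model: duplicate gene ID")
  if (!all(df$strand %in% c("+", "-")))
    stop("read_gene_model: strand must be '+' or '-'")
  if (any(df$gene_start < 0) || any(df$gene_start >= df$gene_end))
    stop("read_gene_model: malformed gene coordinates")
  df
}

#' @rdname read_gene_model
#' @param gene_model data.frame of gene models.
#' @export
write_gene_model <- function(gene_model, path) {
  utils::write.table(gene_model[, gene_model_columns], path, sep = "\t",
                     quote = FALSE, row.names = FALSE, na = "NA")
  invisible(path)
}
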