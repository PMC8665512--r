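# Protein-matrix preprocessing: missingness filter, imputation, and
# high-variance feature selection for clustering.

#' Filter features by missingness
#'
#' Removes features missing in strictly more than `max_missing_fraction`
#' of the samples (a feature missing in exactly half the samples at the
#' default 0.5 is kept). Feature order is preserved.
#'
#' @param m An [omics_matrix()].
#' @param max_missing_fraction Fraction in (0, 1]; default 0.5.
#' @return The filtered matrix.
#' @export
filter_missing <- function(m, max_missing_fraction = 0.5) {
  stopifnot(inherits(m, "omics_matrix"),
            max_missing_fraction > 0, max_missing_fraction <= 1)
  frac <- rowMeans(is.na(m))
  keep <- frac <= max_missing_fraction
  if (!any(keep)) stop("filter_missing: no feature passes the threshold")
  m[keep, ]
}

#' Impute missing entries
#'
#' `half_min` replaces each missing entry with the feature's minimum
#' observed value minus 1 log2 unit (a shifted-minimum rule reflecting
#' intensity-dependent dropout); `knn` averages regression predictions from
#' the `k` most correlated features with an observed value at that sample
#' (falling back to `half_min` when no eligible neighbor exists). Observed
#' entries are never changed.
#'
#' @param m An [omics_matrix()]; every feature must have at least one
#'   observed value.
#' @param method `"half_min"` (default) or `"knn"`.
#' @param k Number of neighbors for `"knn"`.
#' @return The matrix with an empty missingness mask.
#' @export
impute_missing <- function(m, method = c("half_min", "knn"), k = 5) {
  method <- match.arg(method)
  stopifnot(inherits(m, "omics_matrix"), k >= 1)
  x <- unclass(m)
  if (!anyNA(x)) return(m)
  n_obs <- rowSums(!is.na(x))
  if (any(n_obs == 0))
    stop("impute_missing: feature(s) with no observed value (filter first): ",
         paste(utils::head(rownames(x)[n_obs == 0], 5), collapse = ", "))
  half_min_fill <- function(x) {
    fill <- apply(x, 1, min, na.rm = TRUE) - 1
    idx <- which(is.na(x), arr.ind = TRUE)
    x[idx] <- fill[idx[, 1]]
    x
  }
  if (method == "half_min") {
    x <- half_min_fill(x)
  } else {
    mean_f <- rowMeans(x, na.rm = TRUE)
    sd_f <- apply(x, 1, stats::sd, na.rm = TRUE)
    need <- which(rowSums(is.na(x)) > 0)
    out <- x
    for (f in need) {
      miss_s <- which(is.na(x[f, ]))
      # neighbors: correlation over samples shared with f (>= 3 required)
      r <- suppressWarnings(stats::cor(x[f, ], t(x[-f, , drop = FALSE]),
                                       use = "pairwise.complete.obs"))
      r <- drop(r)
      names(r) <- rownames(x)[-f]
      for (s_i in miss_s) {
        cand <- names(r)[!is.na(r) & !is.na(x[names(r), s_i])]
        if (length(cand) == 0) {
          out[f, s_i] <- min(x[f, ], na.rm = TRUE) - 1
          next
        }
        nb <- cand[order(-abs(r[cand]))][seq_len(min(k, length(cand)))]
        pred <- vapply(nb, function(g) {
          shared <- !is.na(x[f, ]) & !is.na(x[g, ])
          if (sum(shared) < 3 || stats::sd(x[g, shared]) == 0)
            return(mean_f[f])
          mf <- mean(x[f, shared]); mg <- mean(x[g, shared])
          sf <- stats::sd(x[f, shared]); sg <- stats::sd(x[g, shared])
          mf + r[g] * sf / sg * (x[g, s_i] - mg)
        }, 0)
        out[f, s_i] <- mean(pred)
      }
    }
    x <- out
  }
  omics_matrix(x, attr(m, "value_domain"))
}

#' Select the most variable features
#'
#' Keeps the `ceiling(fraction * n_features)` features with the highest
#' spread (median absolute deviation by default, the robust choice for
#' heavy-tailed TMT ratios). Ties at the cutoff are broken by feature ID
#' in lexicographic order; input row order is preserved among the kept
#' features.
#'
#' @param m An [omics_matrix()] with no missing values.
#' @param fraction Fraction in (0, 1]; default 0.25.
#' @param metric `"mad"` (default) or `"sd"`.
#' @return The reduced matrix.
#' @export
select_variable <- function(m, fraction = 0.25, metric = c("mad", "sd")) {
  metric <- match.arg(metric)
  stopifnot(inherits(m, "omics_matrix"), fraction > 0, fraction <= 1)
  if (anyNA(m)) stop("select_variable: impute before selecting features")
  x <- unclass(m)
  v <- switch(metric,
              mad = apply(x, 1, stats::mad),
              sd = apply(x, 1, stats::sd))
  n_keep <- ceiling(fraction * nrow(x))
  ord <- order(-v, rownames(x))
  keep <- sort(ord[seq_len(n_keep)])
  m[keep, ]
}
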