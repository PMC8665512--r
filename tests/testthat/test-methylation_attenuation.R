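# DMR calling on M-values, interval annotation semantics, the attenuation
# Gaussian mixture, and hypergeometric over-representation.

make_regions <- function(n, chrom = "chr1") {
  data.frame(chrom = chrom, start = seq_len(n) * 1000,
             end = seq_len(n) * 1000 + 500,
             region_id = sprintf("R%03d", seq_len(n)),
             linked_gene = NA_character_, stringsAsFactors = FALSE)
}

test_that("identical methylation across subgroups yields no DMRs", {
  set.seed(41)
  n <- 30
  beta <- matrix(rep(runif(20), n), 20, n)
  rg <- make_regions(20)
  m <- omics_matrix(`dimnames<-`(beta, list(rg$region_id,
                                            sprintf("S%02d", 1:n))), "beta")
  lab <- stats::setNames(rep(1:3, each = 10), colnames(m))
  dm <- call_dmrs(m, rg, lab, verbose = FALSE)
  expect_identical(sum(dm$dmr), 0L)
})

test_that("betas at 0 and 1 are clipped to a finite statistic", {
  n <- 12
  beta <- rbind(c(rep(0, 6), rep(1, 6)), rep(0.5, 12))
  rg <- make_regions(2)
  m <- omics_matrix(`dimnames<-`(beta, list(rg$region_id,
                                            sprintf("S%02d", 1:n))), "beta")
  lab <- stats::setNames(rep(1:2, each = 6), colnames(m))
  dm <- call_dmrs(m, rg, lab, verbose = FALSE)
  expect_true(all(is.finite(dm$H)))
  expect_true(dm$dmr[1])
  expect_equal(dm$max_delta_beta[1], 1, tolerance = 1e-12)
})

test_that("sex-chromosome regions are dropped before testing", {
  set.seed(42)
  rg <- rbind(make_regions(5), make_regions(5, "chrX"))
  rg$region_id <- sprintf("R%03d", 1:10)
  beta <- matrix(runif(10 * 9), 10, 9,
                 dimnames = list(rg$region_id, sprintf("S%d", 1:9)))
  m <- omics_matrix(beta, "beta")
  lab <- stats::setNames(rep(1:3, each = 3), colnames(m))
  expect_message(dm <- call_dmrs(m, rg, lab), "non-autosomal")
  expect_identical(nrow(dm), 5L)
  expect_false(any(grepl("chrX", dm$chrom)))
})

test_that("a planted 0.3 beta shift is recovered in almost every cohort", {
  hits <- 0
  for (i in 1:50) {
    set.seed(700 + i)
    n <- 77
    lab <- stats::setNames(rep(1:3, c(26, 26, 25)), sprintf("S%03d", 1:n))
    base <- stats::plogis(matrix(rnorm(40 * n, 0, 0.4), 40, n))
    # region 1: subgroup 1 shifted by +0.3 in beta
    base[1, lab == 1] <- pmin(base[1, lab == 1] + 0.3, 1)
    rg <- make_regions(40)
    m <- omics_matrix(`dimnames<-`(base, list(rg$region_id, names(lab))),
                      "beta")
    dm <- call_dmrs(m, rg, lab, alpha = 0.05, verbose = FALSE)
    if (dm$dmr[1]) hits <- hits + 1
  }
  expect_gte(hits, 48)  # >= 95% of 50 seeds
})

test_that("promoter/gene-body/intergenic annotation is half-open exact", {
  gm <- data.frame(gene = c("GP", "GM"), chrom = "chr1",
                   tss = c(10000, 51999), strand = c("+", "-"),
                   gene_start = c(10000, 40000), gene_end = c(30000, 52000),
                   stringsAsFactors = FALSE)
  rg <- data.frame(chrom = "chr1",
                   start = c(35000, 9900, 11500, 11499, 20000, 50800),
                   end = c(35200, 10100, 11501, 11500, 20500, 50900),
                   region_id = sprintf("R%d", 1:6),
                   linked_gene = NA_character_, stringsAsFactors = FALSE)
  ann <- annotate_regions(rg, gm, promoter_window = 1500)
  expect_identical(ann$annotation[1], "intergenic")     # between genes
  expect_identical(ann$annotation[2], "promoter")       # spans + strand TSS
  expect_identical(ann$linked_gene[2], "GP")
  # 1-bp region exactly at TSS+window: promoter interval is half-open
  expect_identical(ann$annotation[3], "gene_body")
  expect_identical(ann$annotation[4], "promoter")       # last promoter base
  expect_identical(ann$annotation[5], "gene_body")
  expect_identical(ann$linked_gene[5], "GP")
  expect_identical(ann$annotation[6], "promoter")       # - strand TSS
  expect_identical(ann$linked_gene[6], "GM")
  expect_error(annotate_regions(
    data.frame(chrom = "chr1", start = 10, end = 5, region_id = "B",
               linked_gene = NA), gm), "coordinates")
})

test_that("the mixture recovers planted components and fractions", {
  set.seed(43)
  x <- c(rnorm(1600, 0, 0.1), rnorm(400, 0.5, 0.1))
  fit <- fit_gmm2(x)
  expect_false(fit$degenerate)
  expect_lt(abs(min(fit$means) - 0), 0.05)
  expect_lt(abs(max(fit$means) - 0.5), 0.05)
  att <- fit$posterior[, which.max(fit$means)] >= 0.5
  expect_lt(abs(mean(att) - 0.2), 0.03)
  # label invariance: flipped initialization, same classification
  fit2 <- fit_gmm2(x, init_means = rev(fit$means))
  att2 <- fit2$posterior[, which.max(fit2$means)] >= 0.5
  expect_identical(att, att2)
  # EM log-likelihood never decreases
  expect_true(all(diff(fit$loglik_trace) >= -1e-7))
})

test_that("degenerate inputs fall back to a single component", {
  fit <- fit_gmm2(rep(0, 100))
  expect_true(fit$degenerate)
  expect_identical(fit$weights[2], 0)
})

test_that("attenuated genes are classified with high sensitivity/specificity", {
  sens <- spec <- numeric(10)
  for (i in 1:10) {
    co <- simulate_cohort(cohort_spec(n_samples = 77, n_genes = 2000,
                                      n_regions = 2600, seed = 800 + i))
    # analyze every promoter-linked gene (the paired-gene universe)
    links <- co$regions[!is.na(co$regions$linked_gene),
                        c("region_id", "linked_gene")]
    imp <- impute_missing(filter_missing(co$protein))
    at <- attenuation_gmm(co$methylation, co$mrna, imp, links)
    rec <- at$records
    truth <- rec$gene %in% co$truth$attenuated_genes
    sens[i] <- mean(rec$attenuated[truth])
    spec[i] <- mean(!rec$attenuated[!truth])
  }
  expect_gte(mean(sens), 0.8)
  expect_gte(mean(spec), 0.9)
})

test_that("attenuation analysis rejects undersized inputs", {
  co <- simulate_cohort(small_spec(seed = 44))
  links <- co$regions[!is.na(co$regions$linked_gene),
                      c("region_id", "linked_gene")][1:5, ]
  imp <- impute_missing(filter_missing(co$protein))
  expect_error(attenuation_gmm(co$methylation, co$mrna, imp, links),
               "< 20")
})

test_that("hypergeometric ORA matches the closed form", {
  k <- 6
  path <- sprintf("A%d", 1:k)
  universe <- c(path, sprintf("B%d", 1:k))
  db <- pathway_db(list(P = path))
  res <- hypergeom_ora(path, universe, db)
  expect_equal(res$p, 1 / choose(2 * k, k), tolerance = 1e-12)
  # empty hit set -> p = 1
  res0 <- hypergeom_ora(character(0), universe, db)
  expect_equal(res0$p, 1)
  expect_error(hypergeom_ora("Z9", universe, db), "subset")
  # uniform draws give calibrated p-values
  set.seed(45)
  u <- sprintf("g%03d", 1:200)
  db2 <- pathway_db(list(P = u[1:20]))
  ps <- replicate(300, hypergeom_ora(sample(u, 30), u, db2)$p)
  expect_lte(mean(ps < 0.05), 0.07)
})
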