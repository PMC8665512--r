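# Pairing, per-gene correlation against a rank-formula oracle, BH step-up,
# and KS pathway enrichment (degenerate cases + permutation calibration).

test_that("pairing intersects features and samples and errors when empty", {
  p <- om(matrix(1:6 * 1.0, 3, 2), features = c("A", "B", "C"),
          samples = c("S1", "S2"))
  m <- om(matrix(1:6 * 1.0, 3, 2), features = c("B", "C", "D"),
          samples = c("S1", "S2"))
  pd <- pair_genes(p, m)
  expect_identical(pd$genes, c("B", "C"))
  expect_identical(pd$n_pairs, 2L)
  m2 <- om(matrix(1:6 * 1.0, 3, 2), features = c("B", "C", "D"),
           samples = c("T1", "T2"))
  expect_error(pair_genes(p, m2), "samples")
  m3 <- om(matrix(1:6 * 1.0, 3, 2), features = c("X", "Y", "Z"),
           samples = c("S1", "S2"))
  expect_error(pair_genes(p, m3), "gene")
})

test_that("a perfectly monotone pair gets rho 1 and a vanishing p", {
  x <- matrix(c(1:8, exp(1:8)), 2, 8, byrow = TRUE)
  pd <- pair_genes(om(x[1, , drop = FALSE], features = "G"),
                   om(x[2, , drop = FALSE], features = "G"))
  cr <- correlate_expression(pd)
  expect_equal(cr$records$rho, 1)
  expect_lt(cr$records$p, 1e-10)
})

test_that("rho, p and BH match a brute-force rank oracle on 10 genes", {
  set.seed(6)
  n <- 15
  prot <- om(matrix(rnorm(10 * n), 10, n))
  mrna <- om(matrix(rnorm(10 * n), 10, n))
  cr <- correlate_expression(pair_genes(prot, mrna))
  # oracle: Pearson on ranks + t-approximation p, independent BH
  g <- sort(rownames(prot))
  rho_o <- p_o <- numeric(10)
  for (i in seq_along(g)) {
    rx <- rank(unclass(mrna)[g[i], ]); ry <- rank(unclass(prot)[g[i], ])
    r <- sum((rx - mean(rx)) * (ry - mean(ry))) /
      sqrt(sum((rx - mean(rx))^2) * sum((ry - mean(ry))^2))
    tt <- r * sqrt((n - 2) / (1 - r^2))
    rho_o[i] <- r
    p_o[i] <- 2 * stats::pt(-abs(tt), n - 2)
  }
  expect_equal(cr$records$rho, rho_o, tolerance = 1e-10)
  expect_equal(cr$records$p, p_o, tolerance = 1e-10)
  expect_equal(cr$records$adj_p, bh_oracle(p_o), tolerance = 1e-10)
})

test_that("Spearman correlation is exactly invariant to monotone transforms", {
  set.seed(7)
  prot <- om(matrix(rnorm(5 * 20), 5, 20))
  mrna <- om(matrix(rnorm(5 * 20), 5, 20))
  a <- correlate_expression(pair_genes(prot, mrna))
  b <- correlate_expression(pair_genes(om(exp(unclass(prot))),
                                       om(qnorm(pnorm(unclass(mrna)) * 0.999))))
  expect_identical(a$records$rho, b$records$rho)
})

test_that("constant vectors are flagged and excluded from BH", {
  x <- matrix(rnorm(3 * 10), 3, 10)
  x[2, ] <- 4
  cr <- correlate_expression(pair_genes(om(x), om(matrix(rnorm(30), 3, 10))))
  expect_true(cr$records$flagged[cr$records$gene == "F02"])
  expect_true(is.na(cr$records$adj_p[cr$records$gene == "F02"]))
  expect_identical(cr$summary$n_tested, 2L)
})

test_that("BH step-up matches hand-computed and oracle values", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.5)),
               c(0.04, 0.04, 0.04, 0.5))
  expect_equal(bh_adjust(rep(1, 5)), rep(1, 5))
  expect_equal(bh_adjust(0.037), 0.037)   # m = 1 -> identity
  expect_error(bh_adjust(c(0.1, 1.2)), "\\[0, 1\\]")
  expect_error(bh_adjust(c(0.1, NA)), "NA")
  set.seed(8)
  for (i in 1:10) {
    p <- runif(sample(2:50, 1))
    adj <- bh_adjust(p)
    expect_equal(adj, bh_oracle(p), tolerance = 1e-12)
    expect_true(all(diff(adj[order(p)]) >= -1e-15))  # monotone along sorted p
  }
})

test_that("KS enrichment handles degenerate and separated pathways", {
  set.seed(9)
  scores <- stats::setNames(rnorm(50), sprintf("G%02d", 1:50))
  all_genes <- pathway_db(list(ALL = names(scores)))
  res <- ks_pathway_enrichment(scores, all_genes)
  expect_identical(nrow(res), 0L)
  expect_identical(attr(res, "skipped"), "ALL")
  # non-overlapping supports force D = 1
  sc <- stats::setNames(c(0.9, 0.8, 0.85, 0.7, 0.95,
                          -0.1, 0, 0.05, -0.2, 0.1), sprintf("g%d", 1:10))
  db <- pathway_db(list(UP = sprintf("g%d", 1:5)))
  r <- ks_pathway_enrichment(sc, db)
  expect_equal(r$ks_stat, 1)
  expect_identical(r$direction, 1)
  # too-small pathways are skipped
  db2 <- pathway_db(list(TINY = sprintf("g%d", 1:3)))
  expect_identical(attr(ks_pathway_enrichment(sc, db2), "skipped"), "TINY")
})

test_that("KS enrichment is calibrated under label permutation", {
  set.seed(10)
  scores <- stats::setNames(rnorm(200), sprintf("G%03d", 1:200))
  hits <- 0; B <- 1000
  for (b in seq_len(B)) {
    member <- sample(names(scores), 20)
    p <- ks_pathway_enrichment(scores, pathway_db(list(P = member)))$p
    if (p < 0.05) hits <- hits + 1
  }
  expect_lte(hits / B, 0.07)
})

test_that("KS enrichment recovers the planted correlated pathways", {
  co <- simulate_cohort(small_spec(seed = 77))
  cr <- correlate_expression(pair_genes(co$protein, co$mrna))
  rho <- stats::setNames(cr$records$rho, cr$records$gene)
  rho <- rho[!cr$records$flagged]
  enr <- ks_pathway_enrichment(rho, co$pathways)
  planted <- enr$pathway %in% co$truth$correlated_pathways
  expect_true(all(enr$adj_p[planted] < 0.01))
  expect_true(all(enr$direction[planted] == 1))
  expect_gt(min(enr$mean_score[planted]), 0.3)
  expect_gt(mean(enr$adj_p[!planted] > 0.05), 0.8)
})

test_that("recovery of planted correlations improves with sample size", {
  frac <- vapply(c(30, 77, 200), function(n) {
    co <- simulate_cohort(cohort_spec(n_samples = n, n_genes = 250,
                                      n_regions = 375, n_pathways = 12,
                                      seed = 1234))
    cr <- correlate_expression(pair_genes(co$protein, co$mrna), alpha = 0.01)
    rec <- cr$records
    planted <- rec$gene %in% co$truth$positively_correlated_genes
    sig <- !rec$flagged & rec$adj_p < 0.01 & rec$rho > 0
    mean(sig[planted])
  }, 0)
  expect_true(frac[1] < frac[2] && frac[2] <= frac[3])
  expect_gt(frac[3], frac[1])
})
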