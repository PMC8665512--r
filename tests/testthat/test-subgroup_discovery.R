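# Consensus clustering recovery and determinism, Kruskal-Wallis DE with
# rank-formula oracles, clinical association, signature scores, overlaps.

test_that("well-separated subgroups are recovered with the right K", {
  co <- simulate_cohort(small_spec(seed = 21, subgroup_shift = 1.2))
  vm <- select_variable(impute_missing(filter_missing(co$protein)))
  cl <- consensus_cluster(vm, k_range = 2:5, n_resamples = 100, seed = 4)
  expect_identical(cl$k, 3L)
  expect_gte(ari(cl$labels, co$truth$subgroup_of_sample[names(cl$labels)]),
             0.9)
  # same seed -> identical labels
  cl2 <- consensus_cluster(vm, k_range = 2:5, n_resamples = 100, seed = 4)
  expect_identical(cl$labels, cl2$labels)
  expect_equal(cl$selection_trace, cl2$selection_trace)
})

test_that("duplicated samples always co-cluster", {
  set.seed(22)
  base <- matrix(rnorm(40 * 6), 40, 6) +
    rep(c(0, 4, 8), each = 2 * 40)[1:(40 * 6)]
  x <- cbind(base, base)
  colnames(x) <- sprintf("S%02d", 1:12)
  rownames(x) <- sprintf("F%02d", 1:40)
  m <- omics_matrix(x)
  cl <- consensus_cluster(m, k_range = 3:3, n_resamples = 60,
                          subsample_fraction = 0.9, seed = 1, fixed_k = 3)
  for (i in 1:6)
    expect_equal(cl$consensus[i, i + 6], 1)
})

test_that("consensus entries stay in [0,1] and labels follow sample order", {
  co <- simulate_cohort(small_spec(seed = 23, subgroup_shift = 2))
  vm <- select_variable(impute_missing(filter_missing(co$protein)))
  cl <- consensus_cluster(vm, k_range = 3:3, n_resamples = 80, seed = 2,
                          fixed_k = 3)
  expect_true(all(cl$consensus >= 0 & cl$consensus <= 1))
  expect_true(all(diag(cl$consensus) == 1))
  expect_equal(cl$consensus, t(cl$consensus))
  # permuting the columns permutes the partition consistently
  perm <- sample(ncol(vm))
  cl_p <- consensus_cluster(vm[, perm], k_range = 3:3, n_resamples = 80,
                            seed = 2, fixed_k = 3)
  expect_equal(ari(cl_p$labels[names(cl$labels)], cl$labels), 1)
})

test_that("k_range outside [2, n-1] errors", {
  m <- om(matrix(rnorm(40), 4, 10))
  expect_error(consensus_cluster(m, k_range = 1:3), "k_range")
  expect_error(consensus_cluster(m, k_range = 2:10), "k_range")
})

test_that("Kruskal-Wallis H matches the rank formula and handles ties", {
  m <- om(matrix(c(1, 2, 3, 4, 5, 6, 7, 8, 9), 1, 9), features = "G")
  lab <- stats::setNames(rep(1:3, each = 3), colnames(m))
  de <- kw_differential(m, lab)
  expect_equal(de$H, 7.2, tolerance = 1e-12)   # 12/(N(N+1)) sum n_i (rbar_i - rbar)^2
  # identical values in all groups -> H = 0
  m0 <- om(matrix(5, 1, 9), features = "G")
  expect_equal(kw_differential(m0, lab)$H, 0)
  # KW is exactly invariant to monotone transforms
  set.seed(24)
  x <- matrix(rnorm(5 * 12), 5, 12)
  lab2 <- stats::setNames(rep(1:3, each = 4), sprintf("S%02d", 1:12))
  a <- kw_differential(om(x), lab2)
  b <- kw_differential(om(exp(x)), lab2)
  expect_identical(a$H, b$H)
})

test_that("two-group KW equals the tie-corrected rank-sum chi-square", {
  set.seed(25)
  x <- matrix(sample(1:6, 2 * 14, replace = TRUE) * 1.0, 2, 14)  # forced ties
  lab <- stats::setNames(rep(1:2, each = 7), sprintf("S%02d", 1:14))
  de <- kw_differential(om(x), lab)
  for (i in 1:2) {
    v <- x[i, ]; g <- rep(1:2, each = 7)
    r <- rank(v); n <- length(v); n1 <- 7; n2 <- 7
    R1 <- sum(r[g == 1])
    mu <- n1 * (n + 1) / 2
    ties <- table(r)
    sig2 <- n1 * n2 * (n + 1) / 12 -
      n1 * n2 * sum(ties^3 - ties) / (12 * n * (n - 1))
    z2 <- (R1 - mu)^2 / sig2
    expect_equal(de$H[i], unname(z2), tolerance = 1e-10)
  }
})

test_that("groups smaller than 2 are rejected", {
  m <- om(matrix(rnorm(10), 1, 10))
  lab <- stats::setNames(c(1, rep(2, 9)), colnames(m))
  expect_error(kw_differential(m, lab), ">= 2 samples")
})

test_that("Fisher association matches hypergeometric enumeration", {
  lab <- stats::setNames(rep(1:2, each = 5), sprintf("S%02d", 1:10))
  clin <- data.frame(sample = sprintf("S%02d", 1:10),
                     rfs_months = 10, rfs_event = 0,
                     tnm_stage = "I", afp_high = c(rep(1, 5), rep(0, 5)),
                     thrombus = 0, phenotype = NA_character_,
                     stringsAsFactors = FALSE)
  res <- clinical_association(lab, clin, variables = c("afp_high", "thrombus"))
  p_afp <- res$p[res$variable == "afp_high"]
  expect_equal(p_afp, 2 / choose(10, 5), tolerance = 1e-12)  # [[5,0],[0,5]]
  expect_equal(p_afp, fisher_oracle(matrix(c(5, 0, 0, 5), 2)),
               tolerance = 1e-12)
  # single-level variable is skipped, not tested
  expect_match(res$method[res$variable == "thrombus"], "skipped")
})

test_that("Fisher association p-values are calibrated under independence", {
  set.seed(26)
  ps <- replicate(300, {
    lab <- stats::setNames(sample(1:3, 30, replace = TRUE),
                           sprintf("S%02d", 1:30))
    clin <- data.frame(sample = names(lab), rfs_months = 10, rfs_event = 0,
                       tnm_stage = "I",
                       afp_high = stats::rbinom(30, 1, 0.5), thrombus = 0,
                       phenotype = NA_character_, stringsAsFactors = FALSE)
    res <- clinical_association(lab, clin, variables = "afp_high")
    res$p[1]
  })
  ps <- ps[!is.na(ps)]
  expect_lte(mean(ps < 0.05), 0.07)   # exact test is conservative
  expect_gt(mean(ps), 0.3)
})

test_that("signature scores are local and detect the immune-hot subgroup", {
  # all-zero expression -> all scores 0
  z <- om(matrix(0, 6, 8), features = sprintf("G%d", 1:6))
  db <- pathway_db(list(CT_A = c("G1", "G2"), CT_B = c("G3", "G4")),
                   c(CT_A = "immune", CT_B = "stromal"))
  sc <- signature_scores(z, db)
  expect_true(all(sc$microenvironment_score == 0))
  # raising one signature's genes in one sample moves only that score
  set.seed(27)
  x <- matrix(rnorm(6 * 8), 6, 8,
              dimnames = list(sprintf("G%d", 1:6), sprintf("S%d", 1:8)))
  x2 <- x; x2[c("G1", "G2"), "S1"] <- x2[c("G1", "G2"), "S1"] + 5
  s1 <- signature_scores(omics_matrix(x), db)
  s2 <- signature_scores(omics_matrix(x2), db)
  expect_gt(s2$CT_A[1], s1$CT_A[1])
  # planted immune-hot subgroup separates on the immune score
  co <- simulate_cohort(small_spec(seed = 28))
  sc2 <- signature_scores(co$mrna, co$signatures)
  lab <- co$truth$subgroup_of_sample[sc2$sample]
  kw <- stats::kruskal.test(sc2$immune_score, factor(lab))
  expect_lt(kw$p.value, 0.01)
  str_kw <- stats::kruskal.test(sc2$stroma_score, factor(lab))
  expect_gt(str_kw$p.value, 0.01)  # no stromal difference planted
})

test_that("overlap summary matches brute-force membership counting", {
  sets <- list(a = c("x", "y", "z"), b = c("y", "z", "w"), c = "q")
  ov <- overlap_summary(sets)
  expect_identical(ov$n_exclusive[ov$combination == "a+b"], 2L)
  expect_identical(ov$n_exclusive[ov$combination == "a"], 1L)
  expect_identical(ov$n_exclusive[ov$combination == "c"], 1L)
  expect_identical(ov$n_exclusive[ov$combination == "a+b+c"], 0L)
  expect_identical(ov$n_intersection[ov$combination == "a+b"], 2L)
  # disjoint and identical edge cases
  d <- overlap_summary(list(a = "1", b = "2"))
  expect_identical(d$n_exclusive[d$combination == "a+b"], 0L)
  e <- overlap_summary(list(a = c("1", "2"), b = c("1", "2")))
  expect_identical(e$n_exclusive[e$combination == "a+b"], 2L)
  expect_identical(e$n_exclusive[e$combination == "a"], 0L)
  # random sets vs direct enumeration
  set.seed(29)
  u <- sprintf("g%02d", 1:40)
  rs <- list(p = sample(u, 15), q = sample(u, 20), r = sample(u, 5))
  ov2 <- overlap_summary(rs)
  for (i in seq_len(nrow(ov2))) {
    inc <- strsplit(ov2$combination[i], "+", fixed = TRUE)[[1]]
    exc <- setdiff(names(rs), inc)
    members <- Reduce(intersect, rs[inc])
    expect_identical(ov2$n_intersection[i], length(members))
    expect_identical(ov2$n_exclusive[i],
                     length(setdiff(members, unlist(rs[exc]))))
  }
})

test_that("null subgroup labels keep the DE false-positive count in check", {
  set.seed(30)
  counts <- vapply(1:10, function(i) {
    x <- matrix(rnorm(200 * 30), 200, 30)
    m <- om(x, features = sprintf("G%03d", 1:200))
    lab <- stats::setNames(sample(rep(1:3, each = 10)), colnames(m))
    sum(kw_differential(m, lab, alpha = 0.05)$significant)
  }, 0)
  expect_lte(mean(counts), 0.05 * 200)
})
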