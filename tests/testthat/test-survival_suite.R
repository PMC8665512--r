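# Early-relapse semantics, exact proportion tests, KM/log-rank against a
# hand-computed table, Cox identities and null behavior, marker screen.

toy_clinical <- function(months, events, samples = sprintf("P%02d",
                                                           seq_along(months)),
                         tnm = "I", afp = 0, thr = 0, pheno = NA_character_) {
  data.frame(sample = samples, rfs_months = months, rfs_event = events,
             tnm_stage = tnm, afp_high = afp, thrombus = thr,
             phenotype = pheno, stringsAsFactors = FALSE)
}

test_that("early relapse is event within horizon; early censoring is NA", {
  cl <- toy_clinical(c(12, 30, 10, 24, 25), c(1, 0, 0, 1, 1))
  fl <- early_relapse_flag(cl, 24)
  expect_identical(unname(fl), c(1L, 0L, NA_integer_, 1L, 0L))
})

test_that("pairwise Fisher tests match enumeration and skip empty strata", {
  flags <- stats::setNames(c(rep(1L, 8), rep(0L, 2), rep(1L, 2), rep(0L, 8)),
                           sprintf("P%02d", 1:20))
  labels <- stats::setNames(rep(c("S1", "S2"), each = 10), names(flags))
  res <- relapse_proportion_test(flags, labels)
  expect_equal(res$p, fisher_oracle(matrix(c(8, 2, 2, 8), 2, byrow = TRUE)),
               tolerance = 1e-12)
  expect_equal(res$p, 0.023, tolerance = 0.001)
  # identical proportions sit at the p ~ 1 end of the exact distribution
  flags2 <- stats::setNames(rep(c(1L, 0L), 10), names(flags))
  res2 <- relapse_proportion_test(flags2, labels)
  expect_gte(res2$p, 0.99)
  # a stratum with an empty margin is skipped with a note
  strat <- stats::setNames(rep(c("I", "II"), each = 10), names(flags))
  res3 <- relapse_proportion_test(flags, labels, strata = strat)
  expect_true(length(attr(res3, "skipped")) > 0 || nrow(res3) < 2)
})

test_that("log-rank matches the hand-computed two-group table", {
  cl <- toy_clinical(c(1, 2, 3, 4, 5, 6), rep(1, 6))
  labels <- stats::setNames(rep(c("A", "B"), each = 3), cl$sample)
  km <- km_logrank(cl, labels)
  # hand table: O_A = 3, E_A = 0.5 + 0.4 + 0.25, V = 0.25 + 0.24 + 3/16
  E <- 0.5 + 2 / 5 + 1 / 4
  V <- 9 / 36 + 6 / 25 + 3 / 16
  expect_equal(km$chisq, (3 - E)^2 / V, tolerance = 1e-10)
  expect_identical(km$df, 1L)
})

test_that("log-rank degenerate cases behave as defined", {
  cl <- toy_clinical(c(5, 6, 7, 8), c(0, 0, 0, 0))
  labels <- stats::setNames(rep(c("A", "B"), 2), cl$sample)
  expect_error(km_logrank(cl, labels), "no events")
  # two groups with identical data -> chi-square 0, p = 1
  cl2 <- toy_clinical(rep(c(2, 4, 6, 8), 2), rep(c(1, 0, 1, 1), 2))
  labels2 <- stats::setNames(rep(c("A", "B"), each = 4), cl2$sample)
  km <- km_logrank(cl2, labels2)
  expect_lt(km$chisq, 1e-10)
  expect_gt(km$p, 0.999)
  # relabeling groups leaves the statistic unchanged
  labels3 <- stats::setNames(ifelse(labels2 == "A", "B", "A"), cl2$sample)
  expect_equal(km_logrank(cl2, labels3)$chisq, km$chisq, tolerance = 1e-12)
})

test_that("KM with no censoring equals the empirical survival function", {
  set.seed(51)
  t <- round(rexp(40, 0.1), 1) + 0.1
  cl <- toy_clinical(t, rep(1, 40), sprintf("P%02d", 1:40))
  labels <- stats::setNames(rep(c("A", "B"), each = 20), cl$sample)
  km <- km_logrank(cl, labels)
  for (grp in c("A", "B")) {
    cv <- km$curves[km$curves$group == grp, ]
    tg <- t[labels == grp]
    emp <- vapply(cv$time, function(u) mean(tg > u), 0)
    expect_equal(cv$surv, emp, tolerance = 1e-12)
  }
})

test_that("administrative censoring never increases the event count", {
  set.seed(52)
  co <- simulate_cohort(small_spec(seed = 52))
  cl <- co$clinical
  labels <- co$truth$subgroup_of_sample
  km_all <- km_logrank(cl, labels)
  km_24 <- km_logrank(cl, labels, horizon_months = 24)
  expect_lte(km_24$n_events, km_all$n_events)
})

test_that("Cox score test at beta = 0 equals the log-rank chi-square", {
  set.seed(53)
  t <- rexp(60, 0.1) + runif(60) * 1e-4     # continuous: no ties
  grp <- rep(0:1, each = 30)
  cl <- toy_clinical(t, rep(1, 60), sprintf("P%02d", 1:60))
  cl$grp <- grp
  labels <- stats::setNames(ifelse(grp == 1, "high", "low"), cl$sample)
  km <- km_logrank(cl, labels)
  cx <- cox_multivariable(cl, labels = labels, covariates = character(0))
  expect_equal(unname(cx$score_chisq), km$chisq, tolerance = 1e-8)
})

test_that("a covariate independent of outcome estimates near zero", {
  ok <- 0
  for (i in 1:20) {
    set.seed(900 + i)
    n <- 500
    cl <- toy_clinical(rexp(n, 0.1), rep(1, n), sprintf("P%03d", 1:n))
    extra <- data.frame(x = rnorm(n), row.names = cl$sample)
    cx <- cox_multivariable(cl, covariates = character(0), extra = extra)
    if (abs(cx$coefficients$coef[1]) <= 0.1) ok <- ok + 1
  }
  expect_gte(ok, 18)  # >= 90% of seeds
})

test_that("duplicating every subject leaves the Cox estimate unchanged", {
  set.seed(54)
  n <- 40
  x <- rnorm(n)
  t <- rexp(n, exp(0.5 * x) * 0.1)
  cl <- toy_clinical(t, rep(1, n), sprintf("P%03d", 1:n))
  cl$x <- x
  cl2 <- cl; cl2$sample <- sprintf("Q%03d", 1:n)
  both <- rbind(cl, cl2)
  # the classical invariance is exact for the untied (Breslow) likelihood;
  # duplication manufactures ties, so Efron's correction is switched off
  c1 <- cox_multivariable(cl, covariates = character(0), ties = "breslow",
                          extra = data.frame(x = x, row.names = cl$sample))
  c2 <- cox_multivariable(both, covariates = character(0), ties = "breslow",
                          extra = data.frame(x = rep(x, 2),
                                             row.names = both$sample))
  expect_equal(c2$coefficients$coef, c1$coefficients$coef, tolerance = 1e-6)
})

test_that("perfect separation is reported as a named error", {
  # events only in one covariate level, with the other level censored late
  cl <- toy_clinical(c(1, 2, 3, 4, 50, 60, 70, 80),
                     c(1, 1, 1, 1, 0, 0, 0, 0))
  extra <- data.frame(sep = c(1, 1, 1, 1, 0, 0, 0, 0),
                      row.names = cl$sample)
  expect_error(cox_multivariable(cl, covariates = character(0),
                                 extra = extra), "sep")
})

test_that("the marker screen finds planted MI/MA markers", {
  found <- 0
  for (i in 1:20) {
    co <- simulate_cohort(cohort_spec(n_samples = 77, n_genes = 200,
                                      n_regions = 300, n_pathways = 12,
                                      seed = 950 + i))
    imp <- impute_missing(filter_missing(co$protein))
    ms <- try(marker_screen(imp, co$clinical), silent = TRUE)
    if (inherits(ms, "try-error")) next
    if (any(ms$passed & ms$protein %in% co$truth$marker_genes))
      found <- found + 1
  }
  expect_gte(found / 20, 0.7)
})

test_that("constant proteins are skipped and null screens stay quiet", {
  set.seed(55)
  n <- 60
  cl <- toy_clinical(round(rexp(n, 0.05), 1), rbinom(n, 1, 0.6),
                     sprintf("P%03d", 1:n),
                     pheno = sample(c("MI", "MA"), n, replace = TRUE))
  x <- matrix(rnorm(1000 * n), 1000, n,
              dimnames = list(sprintf("G%04d", 1:1000), cl$sample))
  x[1, ] <- 3  # constant protein can never split at the median
  ms <- marker_screen(omics_matrix(x), cl)
  expect_false("G0001" %in% ms$protein)
  expect_lte(sum(ms$passed), 2)  # ~<= 1 false marker expected under the null
})
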