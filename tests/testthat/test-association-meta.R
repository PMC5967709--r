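test_that("Firth fit on a saturated 2x2 equals the +0.5-cell closed form", {
  x <- c(rep(1, 10), rep(0, 10))
  y <- c(rep(1, 8), rep(0, 2), rep(1, 2), rep(0, 8))
  fit <- firth_glm(cbind(1, x), y)
  expect_equal(unname(fit$beta[2]), log(8.5 * 8.5 / (2.5 * 2.5)),
               tolerance = 1e-6)
  # independent brute-force maximization of the same penalized likelihood
  oracle <- firth_grid_oracle(cbind(1, x), y)
  expect_equal(unname(fit$beta), unname(oracle), tolerance = 1e-4)
})

test_that("Firth estimates stay finite under complete separation", {
  # all carriers are cases
  x <- c(rep(1, 6), rep(0, 14))
  y <- c(rep(1, 6), rep(1, 4), rep(0, 10))
  fit <- firth_glm(cbind(1, x), y)
  expect_true(all(is.finite(fit$beta)))
  expect_true(all(is.finite(fit$se)))
  oracle <- firth_grid_oracle(cbind(1, x), y)
  expect_equal(unname(fit$beta), unname(oracle), tolerance = 1e-4)
})

test_that("Firth association respects MAC and call-rate filters", {
  set.seed(3)
  g <- cbind(stats::rbinom(100, 2, 0.3), 0, stats::rbinom(100, 2, 0.3))
  colnames(g) <- c("1:1:A:G", "1:2:C:T", "1:3:G:A")
  g[1:30, 3] <- NA  # call rate 0.7
  gm <- genotype_matrix(g, phenotype = rep(c(0, 1), 50))
  ok <- firth_logistic_fit(gm, "1:1:A:G")
  expect_false(ok$skipped)
  expect_true(is.finite(ok$beta_hat))
  mac0 <- firth_logistic_fit(gm, "1:2:C:T")
  expect_true(mac0$skipped)
  expect_match(mac0$reason, "minor allele count")
  lowcr <- firth_logistic_fit(gm, "1:3:G:A")
  expect_true(lowcr$skipped)
  expect_match(lowcr$reason, "call_rate")
})

test_that("Firth estimate is near zero for a null covariate-free design", {
  set.seed(5)
  eff <- effect_table(data.frame(key = "1:1:A:G", beta = 0,
                                 freq_AJ = 0.3))
  gm <- sim_case_control(500, eff, "AJ", beta0 = -0.5, seed = 9)
  fit <- firth_logistic_fit(gm, "1:1:A:G")
  expect_lt(abs(fit$beta_hat), 3 * fit$se)
})

test_that("Wakefield ABF matches the closed form and its limits", {
  expect_equal(wakefield_abf(0.2, 0.1, 0.2), sqrt(0.2) * exp(1.6),
               tolerance = 1e-12)
  # null estimate favours the null
  expect_lt(wakefield_abf(0, 0.1, 0.2), 1)
  expect_equal(wakefield_abf(0, 0.1, 0.2), sqrt(0.01 / 0.05))
  # prior collapsing to the point null: BF -> 1
  expect_equal(wakefield_abf(0.3, 0.1, 1e-8), 1, tolerance = 1e-4)
  # monotone in |z| at fixed se
  bf <- wakefield_abf(seq(0, 1, by = 0.1), 0.1, 0.2)
  expect_true(all(diff(bf) > 0))
  expect_error(wakefield_abf(0.1, 0), "positive")
})

test_that("meta-analysis closed forms: single study and K-study collapse", {
  one <- data.frame(study = "s1", beta_hat = 0.25, se = 0.08)
  m1 <- meta_bayes(one)
  expect_equal(m1$bf_correlated, wakefield_abf(0.25, 0.08),
               tolerance = 1e-12)
  expect_equal(m1$bf_independent, m1$bf_correlated, tolerance = 1e-12)

  two <- data.frame(study = c("a", "b"), beta_hat = 0.2, se = 0.1)
  m2 <- meta_bayes(two)
  expect_equal(m2$bf_correlated, sqrt(0.005 / 0.045) * exp(0.04 * 8 / 0.09),
               tolerance = 1e-10)
  # K identical studies equal one study at se/sqrt(K)
  for (K in c(2, 3, 5)) {
    mk <- meta_bayes(data.frame(study = seq_len(K), beta_hat = 0.17,
                                se = 0.09))
    expect_equal(mk$bf_correlated, wakefield_abf(0.17, 0.09 / sqrt(K)),
                 tolerance = 1e-10)
  }
})

test_that("opposite effects trigger the heterogeneity flag", {
  het <- meta_bayes(data.frame(study = c("a", "b"),
                               beta_hat = c(1, -1), se = 0.1))
  expect_gt(het$bf_independent / het$bf_correlated, 100)
  expect_true(het$heterogeneity_flag)
  hom <- meta_bayes(data.frame(study = c("a", "b"),
                               beta_hat = c(0.2, 0.21), se = 0.1))
  expect_false(hom$heterogeneity_flag)
})

test_that("false-discovery-one threshold is 1/n and selects at the boundary", {
  expect_equal(qq_fd_threshold(runif(351))$threshold, 1 / 351)
  one <- qq_fd_threshold(0.4)
  expect_equal(one$threshold, 1)
  expect_equal(one$selected, 1L)
  got <- qq_fd_threshold(c(0.0005, 1 / 1000, 0.5, rep(0.3, 997)))
  expect_equal(got$selected, c(1L, 2L))  # p <= t inclusive
  expect_error(qq_fd_threshold(numeric()), "at least one")
})

test_that("uniform p-values yield about one annotation on average", {
  set.seed(21)
  counts <- vapply(1:200, function(i)
    length(qq_fd_threshold(stats::runif(1000))$selected), 0L)
  expect_equal(mean(counts), 1, tolerance = 0.25)
})

test_that("GWAS-locus stratification applies the 50 kb flank per chromosome", {
  loci <- data.frame(chrom = c("1", "2"), start = c(1e6, 5e6),
                     end = c(1.2e6, 5.1e6))
  keys <- c("1:1210000:A:G",   # 10 kb beyond span -> gwas
            "1:1260001:A:G",   # 60 kb beyond -> non-gwas
            "1:950001:A:G",    # within upstream flank -> gwas
            "2:5050000:A:G",   # inside span -> gwas
            "2:949999:A:G",    # wrong position entirely
            "3:1100000:A:G")   # right position, wrong chromosome
  expect_equal(stratify_gwas_loci(keys, loci),
               c("gwas", "non-gwas", "gwas", "gwas", "non-gwas",
                 "non-gwas"))
  expect_error(stratify_gwas_loci(keys,
    data.frame(chrom = "1", start = 10, end = 5)), "start <= end")
})
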