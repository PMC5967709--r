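test_that("bias-corrected log odds ratio matches hand-evaluated values", {
  b <- bias_corrected_log_or(10, 990, 5, 9995)
  expect_equal(b$beta_hat, 2.9583, tolerance = 1e-4)
  expect_equal(b$se, 0.5274, tolerance = 1e-4)

  sym <- bias_corrected_log_or(5, 5, 5, 5)
  expect_equal(sym$beta_hat, 0)
  expect_equal(sym$se, sqrt(4 / 5.5), tolerance = 1e-10)

  # finite even with zero cells, and antisymmetric under role swap
  z <- bias_corrected_log_or(0, 100, 7, 0)
  expect_true(is.finite(z$beta_hat) && is.finite(z$se))
  fwd <- bias_corrected_log_or(3, 17, 11, 29)
  rev <- bias_corrected_log_or(11, 29, 3, 17)
  expect_equal(fwd$beta_hat, -rev$beta_hat)
  expect_error(bias_corrected_log_or(-1, 1, 1, 1), "non-negative")
})

test_that("one-sided Fisher p equals hypergeometric enumeration", {
  expect_equal(fisher_one_sided(3, 7, 1, 9), 1410 / 4845,
               tolerance = 1e-12)
  expect_gte(fisher_one_sided(0, 10, 5, 5), 0.999)
  # spot agreement with the choose()-arithmetic oracle and fisher.test
  set.seed(11)
  for (i in 1:25) {
    tab <- as.integer(stats::rmultinom(1, sample(5:30, 1), rep(1, 4)))
    p <- fisher_one_sided(tab[1], tab[2], tab[3], tab[4])
    expect_equal(p, fisher_enum(tab[1], tab[2], tab[3], tab[4]),
                 tolerance = 1e-12)
    ft <- stats::fisher.test(matrix(tab, 2, byrow = TRUE),
                             alternative = "greater")
    expect_equal(p, ft$p.value, tolerance = 1e-8)
  }
})

test_that("p decreases and beta increases as study ALT count grows", {
  alt <- 0:20
  p <- fisher_one_sided(alt, 100 - alt, 10, 1000)
  b <- bias_corrected_log_or(alt, 100 - alt, 10, 1000)$beta_hat
  expect_true(all(diff(p) <= 0))
  expect_true(all(diff(b) > 0))
})

test_that("enrichment classification picks max-frequency reference and windows", {
  rec <- data.frame(
    key = c("1:1:A:G", "1:2:A:G", "1:3:A:G", "1:4:A:G"),
    chrom = "1", pos = 1:4, ref = "A", alt = "G",
    annotation = c("PRA", "SYN", "PTV", "PRA"),
    ac_AJ = c(4L, 87L, 600L, 40L), an_AJ = rep(4000L, 4),
    # v1 below window (AF .001); v3 above window (AF .15); v2, v4 inside
    ac_NFE = c(10L, 60L, 100L, 10L), an_NFE = rep(20000L, 4),
    coverage_ok_NFE = TRUE,
    ac_AFR = c(1L, 2L, 3L, 30L), an_AFR = rep(10000L, 4),
    coverage_ok_AFR = TRUE,
    stringsAsFactors = FALSE)
  res <- classify_enrichment(rec, "AJ", c("NFE", "AFR"))
  expect_equal(res$in_window, c(FALSE, TRUE, FALSE, TRUE))
  expect_false(res$enriched[1])      # AF 0.001 below window
  expect_false(res$enriched[3])      # AF 0.15 above window
  # v4: AFR frequency 0.003 beats NFE 0.0005 -> AFR is the comparator
  expect_equal(res$reference_pop[4], "AFR")
  expect_equal(res$max_ref_af[4], 0.003)
  # v2: NFE 0.003 vs AFR 0.0002 -> AFR ineligible? no: 2e-4 >= 1e-4, NFE wins
  expect_equal(res$reference_pop[2], "NFE")
  expect_equal(attr(res, "n_in_window"), 2)
  # enriched implies in-window, always
  expect_true(all(!res$enriched | res$in_window))
  # deterministic: identical rerun
  expect_identical(res, classify_enrichment(rec, "AJ", c("NFE", "AFR")))
})

test_that("Bonferroni rule with an external test count matches arithmetic", {
  rec <- data.frame(
    key = "1:1:A:G", chrom = "1", pos = 1L, ref = "A", alt = "G",
    annotation = "PRA", ac_AJ = 40L, an_AJ = 4000L,
    ac_NFE = 20L, an_NFE = 60000L, coverage_ok_NFE = TRUE,
    stringsAsFactors = FALSE)
  res <- classify_enrichment(rec, "AJ", "NFE", n_tests = 73228)
  # p for this table is far below 0.05/73228 ~ 6.83e-7
  expect_lt(res$p_one_sided, 0.05 / 73228)
  expect_true(res$enriched)
  # a weaker table clears a lenient threshold but not the Bonferroni one
  weak <- rec
  weak$ac_AJ <- 14L; weak$ac_NFE <- 150L  # AF .0035 vs .0025
  pw <- classify_enrichment(weak, "AJ", "NFE", n_tests = 1)$p_one_sided
  expect_true(pw > 0.05 / 73228 && pw < 0.5)
  expect_false(classify_enrichment(weak, "AJ", "NFE",
                                   n_tests = 73228)$enriched)
  expect_true(classify_enrichment(weak, "AJ", "NFE", alpha = 0.5,
                                  n_tests = 1)$enriched)
})

test_that("variants with no eligible reference are reported unclassifiable", {
  rec <- data.frame(
    key = "1:1:A:G", chrom = "1", pos = 1L, ref = "A", alt = "G",
    annotation = "PRA", ac_AJ = 40L, an_AJ = 4000L,
    ac_NFE = 1L, an_NFE = 60000L,  # AF 1.7e-5 < 1e-4 floor
    coverage_ok_NFE = TRUE, stringsAsFactors = FALSE)
  res <- classify_enrichment(rec, "AJ", "NFE")
  expect_true(is.na(res$reference_pop))
  expect_true(is.na(res$p_one_sided))
  expect_false(res$enriched)
})

test_that("annotation-class proportions and two-proportion test agree with hand formula", {
  mk <- function(class, n, k) data.frame(
    key = paste0(class, seq_len(n)), annotation = class,
    odds_ratio = 2, in_window = TRUE,
    enriched = rep(c(TRUE, FALSE), c(k, n - k)))
  res <- rbind(mk("PRA", 300, 100), mk("SYN", 300, 150))
  out <- annotation_class_proportions(res)
  expect_equal(out$proportions$fraction[out$proportions$class == "PRA"],
               1 / 3)
  expect_equal(out$tests$z[out$tests$class == "PRA"], -4.1404,
               tolerance = 1e-4)
  expect_equal(out$tests$p[out$tests$class == "PRA"], 3.47e-5,
               tolerance = 1e-2)
  # identical proportions give z = 0, p = 1
  res2 <- rbind(mk("PRA", 300, 100), mk("SYN", 300, 100))
  out2 <- annotation_class_proportions(res2)
  expect_equal(out2$tests$z, 0)
  expect_equal(out2$tests$p, 1)
})

test_that("pathogenic intersection excludes conflicted entries and uses strict p", {
  res <- data.frame(
    key = paste0("1:", 1:5, ":A:G"),
    p_one_sided = c(1e-4, 3e-3, 0.005, 1e-6, 0.2),
    enriched = TRUE, stringsAsFactors = FALSE)
  path <- data.frame(
    key = c("1:1:A:G", "1:2:A:G", "1:3:A:G"),
    clinical_significance = "Pathogenic",
    conflicted = c(FALSE, TRUE, FALSE), stringsAsFactors = FALSE)
  out <- intersect_pathogenic(res, path)
  # key 1: pathogenic, p < .005 -> in; key 2 conflicted -> out;
  # key 3: p exactly .005 -> out (strict)
  expect_equal(out$key, "1:1:A:G")
  expect_equal(nrow(intersect_pathogenic(res, path[0, ])), 0)
  expect_error(intersect_pathogenic(res, rbind(path, path[1, ])),
               "duplicate")
})

test_that("recessive risk scales with the squared allele enrichment", {
  expect_identical(recessive_risk_enrichment(19), 361)
  expect_equal(recessive_risk_enrichment(1), 1)
  expect_equal(recessive_risk_enrichment(2.5), 6.25)
  expect_error(recessive_risk_enrichment(0), "positive")
})

test_that("published GBA enrichment OR is reproduced from printed frequencies", {
  t1 <- aj_enriched_pathogenic_table()
  gba <- t1[t1$gene == "GBA", ]
  rec <- enrichment_or_from_freqs(gba$study_af, gba$max_ref_af,
                                  4356, 63804)
  expect_equal(rec$odds_ratio, gba$enrichment_or, tolerance = 0.10)
  # on the log-OR scale every published row with ref AF >= 2e-4 agrees
  keep <- t1$max_ref_af >= 2e-4
  all31 <- enrichment_or_from_freqs(t1$study_af[keep], t1$max_ref_af[keep],
                                    4356, 63804)
  rel_log <- abs(all31$beta_hat - log(t1$enrichment_or[keep])) /
    log(t1$enrichment_or[keep])
  expect_true(all(rel_log < 0.10))
})

test_that("null two-population sampling yields per-variant enrichment rate below alpha/n", {
  # both populations binomial from one frequency; Fisher is conservative
  set.seed(101)
  n_var <- 10000
  f <- stats::runif(n_var, 0.005, 0.05)
  ac_a <- stats::rbinom(n_var, 4000, f)
  ac_b <- stats::rbinom(n_var, 40000, f)
  p <- fisher_one_sided(ac_a, 4000 - ac_a, ac_b, 40000 - ac_b)
  alpha_per <- 0.05 / n_var
  n_hits <- sum(p < alpha_per)
  # expected hits <= n * alpha/n = 0.05; binomial 95% upper bound ~ 2
  expect_lte(n_hits, 2)
})
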