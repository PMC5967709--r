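test_that("liability parameters evaluate the mu and sigma2 sums", {
  eff <- effect_table(data.frame(key = "1:1:A:G", beta = 0.4,
                                 freq_AJ = 0.25))
  lp <- liability_params(eff, "AJ", p0 = 0.005)
  expect_equal(lp$mu, -5.2933 + 0.2, tolerance = 1e-4)
  expect_equal(lp$sigma2, 0.06, tolerance = 1e-12)
  # no variants: mu = logit(p0), sigma2 = 0
  lp0 <- liability_params(eff[0, ], "AJ", p0 = 0.005)
  expect_equal(lp0$mu, stats::qlogis(0.005))
  expect_equal(lp0$sigma2, 0)
  # sigma2 equals the HWE variance of the additive PRS
  set.seed(4)
  effm <- effect_table(data.frame(key = paste0("1:", 1:4, ":A:G"),
                                  beta = c(0.3, -0.5, 0.2, 0.7),
                                  freq_AJ = c(0.1, 0.3, 0.5, 0.02)))
  n <- 50000
  g <- vapply(effm$freq_AJ, function(f) stats::rbinom(n, 2, f), numeric(n))
  colnames(g) <- effm$key
  scores <- compute_prs(genotype_matrix(g, rep(0:1, n / 2)), effm)
  lp2 <- liability_params(effm, "AJ", 0.005)
  # sampling sd of a variance is roughly sigma2 * sqrt(2/(n-1))
  expect_lt(abs(stats::var(scores) - lp2$sigma2),
            4 * lp2$sigma2 * sqrt(2 / (n - 1)) + 1e-4)
  expect_error(liability_params(eff, "AJ", p0 = 0), "\\(0, 1\\)")
})

test_that("expected prevalence integrates the inverse link over the score density", {
  # degenerate sigma: exactly the inverse link
  expect_identical(expected_prevalence(liability_model(-2, 0)),
                   stats::plogis(-2))
  expect_identical(expected_prevalence(liability_model(-2, 0, "probit")),
                   stats::pnorm(-2))
  # hand-checked value (lognormal small-p approximation ~ 0.00628)
  expect_equal(expected_prevalence(liability_model(-5.0933, 0.06)),
               0.00628, tolerance = 1e-3)
  # strictly increasing in mu
  ep <- vapply(seq(-8, 0, by = 1), function(m)
    expected_prevalence(liability_model(m, 0.25)), 0)
  expect_true(all(diff(ep) > 0))
  # Jensen: above g(mu) deep in the convex region
  expect_gt(expected_prevalence(liability_model(-10, 0.5)),
            stats::plogis(-10))
})

test_that("the p-space prevalence density integrates to 1 and matches E[p]", {
  model <- liability_model(-5.0933, 0.06)
  total <- stats::integrate(prevalence_density, 0, 1, model = model,
                            rel.tol = 1e-10, subdivisions = 2000L)
  expect_equal(total$value, 1, tolerance = 1e-8)
  ep <- stats::integrate(function(p) p * prevalence_density(p, model),
                         0, 1, rel.tol = 1e-10, subdivisions = 2000L)
  expect_equal(ep$value, expected_prevalence(model), tolerance = 1e-8)
})

test_that("baseline calibration round-trips and sits below logit(target)", {
  b0 <- calibrate_beta0(0.005)
  expect_equal(b0, stats::qlogis(0.005), tolerance = 1e-9)
  b0v <- calibrate_beta0(0.005, shift = 0.4, sigma2 = 0.1)
  got <- expected_prevalence(liability_model(b0v + 0.4, 0.1))
  expect_equal(got, 0.005, tolerance = 1e-9)
  # risk alleles push prevalence up, so the calibrated baseline is lower
  expect_lt(b0v, stats::qlogis(0.005))
  expect_error(calibrate_beta0(0.005, interval = c(-1, 0)), "unreachable")
})

test_that("prevalence ratio matches the small-p exponential limit and sweeps mildly", {
  pr <- prevalence_ratio(shift_a = 0.3, shift_b = 0, sigma2_a = 0.01,
                         sigma2_b = 0.01, baseline = 0.001, sweep = NULL)
  expect_equal(pr$ratio, exp(0.3), tolerance = 0.02)
  same <- prevalence_ratio(0.2, 0.2, 0.05, 0.05, sweep = NULL)
  expect_equal(same$ratio, 1, tolerance = 1e-9)
  swept <- prevalence_ratio(0.3, 0, 0.05, 0.05)
  expect_equal(nrow(swept$curve), 10)
  rng <- range(swept$curve$ratio)
  expect_lt((rng[2] - rng[1]) / rng[1], 0.10)
  expect_equal(swept$curve$prevalence_b, swept$curve$baseline,
               tolerance = 1e-8)
})

test_that("probit mapping preserves zero, matches normal quantiles and is near-linear", {
  pc <- probit_comparison(liability_model(-0.1, 0.04))
  expect_equal(pc$slope, 0.6223, tolerance = 0.005)
  expect_gte(pc$r_squared, 0.999)
  expect_equal(stats::qnorm(stats::plogis(1)), 0.6160, tolerance = 1e-4)
  expect_identical(stats::qnorm(stats::plogis(0)), 0)
  # equal-probability mapping keeps expected prevalence close across links
  m <- liability_model(-5.0933, 0.06)
  pc2 <- probit_comparison(m)
  expect_equal(pc2$prevalence_probit, expected_prevalence(m),
               tolerance = 0.02 * expected_prevalence(m))
})

test_that("attributable prevalence follows the Moonesinghe factors", {
  # additive one-variant check: (1 + 0.1 * 1)^2 = 1.21
  one <- attributable_prevalence(freq = cbind(A = 0.1), grr = 2,
                                 prevalence = 0.01)
  expect_equal(unname(one$i), 0.01 / 1.21, tolerance = 1e-12)
  # non-additive HWE factor: 1 + 2*0.1*0.9*1 + 0.01*8 = 1.26
  na1 <- attributable_prevalence(freq = cbind(A = 0.1), grr_het = 2,
                                 grr_hom = 9, prevalence = 0.01)
  expect_equal(unname(na1$i), 0.01 / 1.26, tolerance = 1e-12)
  # GRR = 1 leaves prevalence untouched, fraction 0
  null2 <- attributable_prevalence(freq = cbind(A = c(0.1, 0.2),
                                                B = c(0.3, 0.1)),
                                   grr = c(1, 1),
                                   prevalence = c(0.01, 0.02))
  expect_equal(unname(null2$i), c(0.01, 0.02))
  expect_equal(null2$attributable_fraction, 0)
  # equal prevalences: fraction undefined, reported as NA
  eqp <- attributable_prevalence(freq = cbind(A = 0.1, B = 0.1),
                                 grr = 2, prevalence = c(0.01, 0.01))
  expect_true(is.na(eqp$attributable_fraction))
  # non-additive factor reduces to additive when GRR_hom = GRR_het^2
  f <- c(0.05, 0.3); g <- c(1.8, 2.5)
  add <- attributable_prevalence(cbind(A = f), grr = g, prevalence = 0.01)
  red <- attributable_prevalence(cbind(A = f), grr_het = g,
                                 grr_hom = g^2, prevalence = 0.01)
  expect_equal(red$i, add$i, tolerance = 1e-12)
})
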