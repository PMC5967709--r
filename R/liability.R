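#' Construct a liability (risk-score) model
#'
#' In the logit risk model an individual's disease probability is
#' `p = expit(eta)` where the risk score `eta` is approximately normal
#' across the population with mean `mu = logit(p0) + sum 2 f beta`
#' and variance `sigma2 = 2 sum f (1 - f) beta^2` (the Hardy-Weinberg
#' variance of the additive PRS). The probit variant uses
#' `p = Phi(eta)`.
#'
#' @param mu Risk-score mean.
#' @param sigma2 Risk-score variance, non-negative.
#' @param link `"logit"` (default) or `"probit"`.
#' @return Object of class `liability_model`.
#' @export
liability_model <- function(mu, sigma2, link = c("logit", "probit")) {
  link <- match.arg(link)
  if (sigma2 < 0) stop("sigma2 must be non-negative")
  structure(list(mu = mu, sigma2 = sigma2, link = link),
            class = "liability_model")
}

#' Liability parameters from an effect table
#'
#' Evaluates `mu = logit(p0) + sum_m 2 f_m beta_m` and
#' `sigma2 = 2 sum_m f_m (1 - f_m) beta_m^2` for one population.
#'
#' @param effects An [effect_table()].
#' @param population Population label (selects `freq_<pop>`).
#' @param p0 Baseline disease probability in (0, 1) (risk with zero
#'   non-baseline alleles).
#' @param exclude Optional variant keys to exclude.
#' @return List with `mu`, `sigma2`, `beta0 = logit(p0)`.
#' @export
liability_params <- function(effects, population, p0, exclude = NULL) {
  if (p0 <= 0 || p0 >= 1) stop("p0 must lie in (0, 1)")
  eff <- effects
  if (!is.null(exclude)) eff <- eff[!(eff$key %in% exclude), , drop = FALSE]
  f <- if (nrow(eff)) effect_freq(eff, population) else numeric(0)
  beta0 <- stats::qlogis(p0)
  list(mu = beta0 + sum(2 * f * eff$beta),
       sigma2 = 2 * sum(f * (1 - f) * eff$beta^2),
       beta0 = beta0)
}

# E[g(eta)] for eta ~ N(mu, sigma2) by Gauss-Hermite quadrature,
# escalating the node count until successive estimates agree to rel_tol.
gauss_hermite_mean <- function(g, mu, sigma2, nodes = 64,
                               rel_tol = 1e-10, max_nodes = 512) {
  if (sigma2 == 0) return(g(mu))
  s <- sqrt(sigma2)
  est_at <- function(n) {
    gh <- pracma::gaussHermite(n)
    sum(gh$w * g(mu + sqrt(2) * s * gh$x)) / sqrt(pi)
  }
  est <- est_at(nodes)
  repeat {
    nodes <- nodes * 2
    if (nodes > max_nodes)
      stop("quadrature did not converge to relative tolerance ",
           rel_tol, " (last estimate ", format(est), ")")
    est2 <- est_at(nodes)
    # relative convergence with a small absolute floor for means near 0
    if (abs(est2 - est) <= rel_tol * abs(est2) + 1e-12) return(est2)
    est <- est2
  }
}

#' Expected disease prevalence under a liability model
#'
#' `E[p] = integral of g(eta) * N(eta; mu, sigma2) d eta`, with g the
#' inverse link (expit or Phi), evaluated by adaptive Gauss-Hermite
#' quadrature (node count escalated until successive estimates agree to
#' 1e-10 relative). Equals the p-space integral `int p f(p) dp` of the
#' transformed prevalence density by change of variables. With
#' `sigma2 = 0` it returns `g(mu)` exactly.
#'
#' @param model A [liability_model()].
#' @return Scalar expected prevalence in (0, 1).
#' @export
expected_prevalence <- function(model) {
  g <- if (model$link == "logit") stats::plogis else stats::pnorm
  gauss_hermite_mean(g, model$mu, model$sigma2)
}

#' Prevalence density on the probability scale
#'
#' The density of individual disease probability `p = g(eta)` implied
#' by `eta ~ N(mu, sigma2)`:
#' `f(p) = phi((g^-1(p) - mu)/sigma) / (sigma * |g'(g^-1(p))|)`
#' (for the logit link `|g'| = p (1 - p)`). Integrates to 1 and yields
#' the same expectation as [expected_prevalence()].
#'
#' @param p Probability values in (0, 1).
#' @param model A [liability_model()] with `sigma2 > 0`.
#' @return Density values at `p`.
#' @export
prevalence_density <- function(p, model) {
  if (model$sigma2 <= 0) stop("density requires sigma2 > 0")
  s <- sqrt(model$sigma2)
  if (model$link == "logit") {
    eta <- stats::qlogis(p)
    jac <- p * (1 - p)
  } else {
    eta <- stats::qnorm(p)
    jac <- stats::dnorm(eta)
  }
  stats::dnorm((eta - model$mu) / s) / (s * jac)
}

#' Calibrate the baseline risk score to a target prevalence
#'
#' Root-finds `beta0` such that the expected prevalence of the model
#' with `mu = beta0 + shift` equals `target` (shift is the population's
#' expected PRS contribution `sum 2 f beta`). Unique by monotonicity of
#' E[p] in mu.
#'
#' @param target Target prevalence in (0, 1).
#' @param shift Additive risk-score shift on top of the baseline
#'   (default 0).
#' @param sigma2 Risk-score variance (default 0).
#' @param link `"logit"` or `"probit"`.
#' @param interval Search interval for beta0.
#' @return Scalar `beta0`.
#' @export
calibrate_beta0 <- function(target, shift = 0, sigma2 = 0,
                            link = c("logit", "probit"),
                            interval = c(-50, 10)) {
  link <- match.arg(link)
  if (target <= 0 || target >= 1) stop("target must lie in (0, 1)")
  f <- function(b0)
    log(expected_prevalence(liability_model(b0 + shift, sigma2, link))) -
      log(target)
  lo <- f(interval[1]); hi <- f(interval[2])
  if (is.nan(lo) || is.nan(hi) || lo > 0 || hi < 0)
    stop("target prevalence unreachable within the search interval")
  stats::uniroot(f, interval, tol = 1e-12)$root
}

#' Prevalence ratio between two populations, with a baseline sweep
#'
#' Computes `E[p_a] / E[p_b]` for two liability models sharing link and
#' baseline, and tabulates how the ratio varies as the baseline
#' prevalence (hence `beta0`) sweeps a grid: for each grid value,
#' `beta0` is recalibrated so population b attains that baseline
#' prevalence, holding both populations' PRS shifts and variances
#' fixed.
#'
#' @param shift_a,shift_b Expected PRS contribution (`sum 2 f beta`)
#'   of each population.
#' @param sigma2_a,sigma2_b Risk-score variances.
#' @param baseline Baseline prevalence used for the headline ratio
#'   (default 0.005).
#' @param sweep Baseline-prevalence grid for the curve (default
#'   `seq(0.001, 0.01, by = 0.001)`); `NULL` to skip.
#' @param link `"logit"` or `"probit"`.
#' @return List with `ratio`, `prevalence_a`, `prevalence_b`, `beta0`,
#'   and `curve` (data.frame `baseline, beta0, prevalence_a,
#'   prevalence_b, ratio`).
#' @export
prevalence_ratio <- function(shift_a, shift_b, sigma2_a, sigma2_b,
                             baseline = 0.005,
                             sweep = seq(0.001, 0.01, by = 0.001),
                             link = c("logit", "probit")) {
  link <- match.arg(link)
  eval_at <- function(base) {
    b0 <- calibrate_beta0(base, shift = shift_b, sigma2 = sigma2_b,
                          link = link)
    pa <- expected_prevalence(liability_model(b0 + shift_a, sigma2_a, link))
    pb <- expected_prevalence(liability_model(b0 + shift_b, sigma2_b, link))
    c(beta0 = b0, prevalence_a = pa, prevalence_b = pb, ratio = pa / pb)
  }
  head <- eval_at(baseline)
  out <- list(ratio = unname(head["ratio"]),
              prevalence_a = unname(head["prevalence_a"]),
              prevalence_b = unname(head["prevalence_b"]),
              beta0 = unname(head["beta0"]))
  if (!is.null(sweep)) {
    rows <- t(vapply(sweep, eval_at, head))
    out$curve <- data.frame(baseline = sweep, rows)
  }
  out
}

#' Probit comparison of a logit liability model
#'
#' Maps logit risk scores to probit scores through equal probability
#' (`eta_probit = Phi^-1(expit(eta_logit))`), transforming the score
#' density by the Jacobian. Returns the probit-score mean and standard
#' deviation implied by the logit model, the expected prevalence under
#' a normal approximation to the probit score distribution, and the
#' slope and r-squared of a no-intercept least-squares fit of
#' `eta_probit` on `eta_logit` over a 201-point uniform grid on
#' [-1, 1] (the near-linear regime).
#'
#' @param model A logit-link [liability_model()].
#' @return List with `mu_probit`, `sigma_probit`,
#'   `prevalence_probit`, `slope`, `r_squared`.
#' @export
probit_comparison <- function(model) {
  if (model$link != "logit") stop("model must use the logit link")
  to_probit <- function(eta) stats::qnorm(stats::plogis(eta))
  mu_p <- gauss_hermite_mean(to_probit, model$mu, model$sigma2)
  m2 <- gauss_hermite_mean(function(e) to_probit(e)^2,
                           model$mu, model$sigma2)
  sigma_p <- sqrt(max(0, m2 - mu_p^2))
  prev_p <- expected_prevalence(liability_model(mu_p, sigma_p^2, "probit"))
  x <- seq(-1, 1, length.out = 201)
  y <- to_probit(x)
  slope <- sum(x * y) / sum(x^2)
  r2 <- sum(x * y)^2 / (sum(x^2) * sum(y^2))
  list(mu_probit = mu_p, sigma_probit = sigma_p,
       prevalence_probit = prev_p, slope = slope, r_squared = r2)
}

#' Prevalence attributable to implicated variants (Moonesinghe)
#'
#' Computes the disease prevalence each population would have without
#' the risk factors, `i_j = p_j / prod_m (1 + f_mj (GRR_m - 1))^2`
#' (additive mode) or
#' `i_j = p_j / prod_m (1 + 2 f_mj (1 - f_mj) (GRR_het - 1) +
#' f_mj^2 (GRR_hom - 1))` (genotype-specific mode — the
#' Hardy-Weinberg population-average genotype relative risk
#' `(1-f)^2 + 2 f (1-f) GRR_het + f^2 GRR_hom`, which reduces exactly
#' to the additive factor when `GRR_hom = GRR_het^2`), and the
#' fraction of the between-population prevalence difference
#' attributable to them, `((p2 - p1) - (i2 - i1)) / (p2 - p1)`.
#'
#' @param freq Matrix or data.frame of per-variant frequencies, one
#'   column per population (variants in rows).
#' @param grr Vector of genotype relative risks (additive mode), or
#'   `NULL` when `grr_het`/`grr_hom` are given.
#' @param grr_het,grr_hom Genotype-specific relative risks
#'   (non-additive mode).
#' @param prevalence Named or positional vector of observed disease
#'   prevalence per population (aligned with `freq` columns).
#' @return List with `i` (baseline prevalence per population),
#'   `attributable_fraction` (NA with a message when the populations'
#'   prevalences are equal), and `mode`.
#' @export
attributable_prevalence <- function(freq, grr = NULL, grr_het = NULL,
                                    grr_hom = NULL, prevalence) {
  freq <- as.matrix(freq)
  if (any(prevalence <= 0 | prevalence >= 1))
    stop("prevalence values must lie in (0, 1)")
  if (!is.null(grr)) {
    if (any(grr <= 0)) stop("GRR must be positive")
    factor_j <- apply(freq, 2, function(f)
      prod((1 + f * (grr - 1))^2))
    mode <- "additive"
  } else {
    if (is.null(grr_het) || is.null(grr_hom))
      stop("supply either grr, or both grr_het and grr_hom")
    if (any(grr_het <= 0) || any(grr_hom <= 0)) stop("GRR must be positive")
    factor_j <- apply(freq, 2, function(f)
      prod(1 + 2 * f * (1 - f) * (grr_het - 1) + f^2 * (grr_hom - 1)))
    mode <- "nonadditive"
  }
  i <- prevalence / factor_j
  if (ncol(freq) >= 2) {
    dp <- prevalence[2] - prevalence[1]
    af <- if (dp == 0) NA_real_ else (dp - (i[2] - i[1])) / dp
  } else af <- NA_real_
  list(i = i, attributable_fraction = unname(af), mode = mode)
}
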