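#' Simulate founder-bottleneck allele counts
#'
#' Generates a `variant_counts` table for a bottlenecked study
#' population and one or more reference populations. Ancestral allele
#' frequencies are drawn from a 1/x site-frequency spectrum truncated
#' to `[spectrum_min, spectrum_max]`; the founder event is a
#' single-generation binomial bottleneck of `founder_chromosomes`
#' chromosomes (frequency after the bottleneck is the binomial draw
#' divided by the bottleneck size), after which study allele counts are
#' binomial in `2 * n_study` chromosomes at the founder frequency and
#' reference counts are binomial in `2 * n_ref` at the ancestral
#' frequency. Variants lost in the bottleneck (founder frequency 0)
#' are emitted with zero study counts, reproducing the
#' enrichment-and-loss structure a bottleneck induces. Annotation
#' classes are assigned independently of frequency with probabilities
#' `annotation_probs`.
#'
#' @param n_variants Number of variants.
#' @param founder_chromosomes Bottleneck size in chromosomes (e.g.
#'   `2 * N_founder`); large values (1e7) approximate no bottleneck.
#' @param n_study,n_ref Diploid sample sizes of the study population
#'   and each reference population.
#' @param reference_pops Labels of the reference populations (counts
#'   are drawn independently per population from the same ancestral
#'   frequency).
#' @param study_pop Label of the study population.
#' @param spectrum_min,spectrum_max Truncation bounds of the 1/x
#'   ancestral spectrum (defaults 1e-4 and 0.5).
#' @param annotation_probs Named probabilities for PTV/PRA/SYN/OTHER.
#' @param seed Integer seed; identical inputs give identical output.
#' @return A `variant_counts` data.frame (as from
#'   [read_variant_counts()]) with `coverage_ok_*` all TRUE.
#' @export
sim_bottleneck_counts <- function(n_variants, founder_chromosomes,
                                  n_study, n_ref,
                                  reference_pops = "NFE",
                                  study_pop = "AJ",
                                  spectrum_min = 1e-4,
                                  spectrum_max = 0.5,
                                  annotation_probs = c(PTV = 0.05,
                                                       PRA = 0.55,
                                                       SYN = 0.40),
                                  seed = 1) {
  stopifnot(n_variants > 0, founder_chromosomes > 0,
            n_study > 0, n_ref > 0)
  set.seed(as.integer(seed))
  # inverse-CDF draw from density proportional to 1/x on [a, b]
  a <- spectrum_min; b <- spectrum_max
  x <- a * (b / a)^stats::runif(n_variants)
  founder_f <- stats::rbinom(n_variants, founder_chromosomes, x) /
    founder_chromosomes
  an_s <- 2L * as.integer(n_study)
  ac_s <- stats::rbinom(n_variants, an_s, founder_f)
  ann <- sample(names(annotation_probs), n_variants, replace = TRUE,
                prob = annotation_probs)
  out <- data.frame(
    key = variant_key("1", seq_len(n_variants), "A", "G"),
    chrom = "1", pos = seq_len(n_variants), ref = "A", alt = "G",
    annotation = ann, stringsAsFactors = FALSE)
  out[[paste0("ac_", study_pop)]] <- ac_s
  out[[paste0("an_", study_pop)]] <- an_s
  n_ref <- rep_len(n_ref, length(reference_pops))
  for (i in seq_along(reference_pops)) {
    an_r <- 2L * as.integer(n_ref[i])
    out[[paste0("ac_", reference_pops[i])]] <-
      stats::rbinom(n_variants, an_r, x)
    out[[paste0("an_", reference_pops[i])]] <- an_r
    out[[paste0("coverage_ok_", reference_pops[i])]] <- TRUE
  }
  out$ancestral_freq <- x
  out$founder_freq <- founder_f
  structure(out, populations = c(study_pop, reference_pops),
            class = c("variant_counts", "data.frame"))
}

#' Simulate case-control genotypes under a logistic risk model
#'
#' Draws genotypes at Hardy-Weinberg equilibrium from the effect
#' table's frequencies for `population`, then assigns phenotype by a
#' Bernoulli draw with `logit p = beta0 + sum_m beta_m G_m` (additive)
#' or `beta0 + sum_m [beta_het 1(het) + beta_hom 1(hom)]` when the
#' effect table carries genotype-specific effects and
#' `genotype_specific = TRUE`. Optional confounding adds a standard
#' normal covariate with loading `covariate_loading` to the linear
#' predictor; the realized covariate is returned in the matrix.
#'
#' @param n Number of samples.
#' @param effects An [effect_table()].
#' @param population Frequency column used for genotype sampling.
#' @param beta0 Baseline log-odds intercept.
#' @param genotype_specific Use `beta_het`/`beta_hom` coding.
#' @param covariate_loading Effect of a simulated standard-normal
#'   covariate on the log-odds (default 0 = none; the covariate column
#'   is included either way).
#' @param seed Integer seed.
#' @return A `genotype_matrix` with one covariate column `PC1`.
#' @export
sim_case_control <- function(n, effects, population, beta0,
                             genotype_specific = FALSE,
                             covariate_loading = 0, seed = 1) {
  set.seed(as.integer(seed))
  f <- effect_freq(effects, population)
  m <- length(f)
  g <- vapply(seq_len(m), function(j) stats::rbinom(n, 2, f[j]),
              numeric(n))
  g <- matrix(g, nrow = n, dimnames = list(NULL, effects$key))
  pc <- stats::rnorm(n)
  if (genotype_specific) {
    if (!all(c("beta_het", "beta_hom") %in% names(effects)))
      stop("genotype_specific = TRUE requires beta_het/beta_hom")
    eta <- beta0 +
      (g == 1) %*% effects$beta_het + (g == 2) %*% effects$beta_hom
  } else {
    eta <- beta0 + g %*% effects$beta
  }
  eta <- drop(eta) + covariate_loading * pc
  y <- stats::rbinom(n, 1, stats::plogis(eta))
  if (sum(y) == 0 || sum(y) == n)
    stop("degenerate phenotype (all ", if (sum(y) == 0) "controls"
         else "cases", "); adjust beta0 (current ", beta0, ")")
  genotype_matrix(g, y, covariates = cbind(PC1 = pc),
                  sample_ids = paste0("S", seq_len(n)))
}

#' Simulate multi-study association summary statistics
#'
#' Per-study estimates `beta_hat_k ~ N(true_beta + delta_k, se_k^2)`
#' with study-level heterogeneity `delta_k ~ N(0, heterogeneity_sd^2)`
#' (0 = a single shared effect).
#'
#' @param true_beta Shared true log odds ratio.
#' @param se Vector of per-study standard errors (length = number of
#'   studies).
#' @param heterogeneity_sd Standard deviation of study-specific effect
#'   deviations (default 0).
#' @param seed Integer seed.
#' @return data.frame with `study`, `beta_hat`, `se`.
#' @export
sim_multistudy_summaries <- function(true_beta, se, heterogeneity_sd = 0,
                                     seed = 1) {
  if (any(se <= 0)) stop("all se must be positive")
  set.seed(as.integer(seed))
  k <- length(se)
  delta <- stats::rnorm(k, 0, heterogeneity_sd)
  data.frame(study = paste0("study", seq_len(k)),
             beta_hat = stats::rnorm(k, true_beta + delta, se),
             se = se, stringsAsFactors = FALSE)
}
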