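#' Bias-corrected log odds ratio for a 2x2 allele-count table
#'
#' Haldane-Anscombe corrected log odds ratio comparing ALT-allele odds
#' in the study population against a reference population, with 0.5
#' added to every cell so that the estimate and its standard error are
#' finite for any non-negative counts:
#' \deqn{\hat\beta = \log\frac{(0.5+ALT_s)(0.5+REF_r)}{(0.5+REF_s)(0.5+ALT_r)},\quad
#'       \widehat{SE}^2 = \sum_{cells} \frac{1}{0.5+n_{cell}}.}
#'
#' @param alt_study,ref_study ALT and REF allele counts in the study
#'   population.
#' @param alt_ref,ref_ref ALT and REF allele counts in the reference
#'   population.
#' @return List with `beta_hat`, `se` and `odds_ratio = exp(beta_hat)`.
#'   Vectorized over its arguments.
#' @examples
#' bias_corrected_log_or(10, 990, 5, 9995)
#' @export
bias_corrected_log_or <- function(alt_study, ref_study, alt_ref, ref_ref) {
  counts <- cbind(alt_study, ref_study, alt_ref, ref_ref)
  if (any(counts < 0)) stop("allele counts must be non-negative")
  beta_hat <- log((0.5 + alt_study) * (0.5 + ref_ref)) -
    log((0.5 + ref_study) * (0.5 + alt_ref))
  se <- sqrt(1 / (0.5 + alt_study) + 1 / (0.5 + ref_study) +
               1 / (0.5 + alt_ref) + 1 / (0.5 + ref_ref))
  list(beta_hat = beta_hat, se = se, odds_ratio = exp(beta_hat))
}

#' One-sided Fisher exact test for allele enrichment
#'
#' Exact upper hypergeometric tail probability
#' \eqn{P(X \ge ALT_s)} conditioning on the margins of the 2x2
#' allele-count table — the one-sided ("greater") Fisher exact test for
#' the study population carrying an excess of the ALT allele.
#'
#' @inheritParams bias_corrected_log_or
#' @return One-sided p-value in (0, 1]. Vectorized.
#' @export
fisher_one_sided <- function(alt_study, ref_study, alt_ref, ref_ref) {
  if (any(cbind(alt_study, ref_study, alt_ref, ref_ref) < 0))
    stop("allele counts must be non-negative")
  k <- alt_study + alt_ref          # ALT margin
  m <- alt_study + ref_study        # study margin
  n <- alt_ref + ref_ref            # reference margin
  # P(X >= alt_study) for X ~ Hypergeometric(m, n, k)
  p <- stats::phyper(alt_study - 1, m, n, k, lower.tail = FALSE)
  pmin(pmax(p, .Machine$double.xmin), 1)
}

#' Classify founder-population allele enrichment
#'
#' For each variant, picks as comparator the reference population with
#' the highest allele frequency among those with adequate coverage and
#' frequency at least `ref_af_min`, computes the bias-corrected log
#' odds ratio, its standard error and the one-sided Fisher exact
#' p-value, and classifies the variant as enriched if it lies in the
#' study-frequency window and its p-value beats the Bonferroni
#' threshold `alpha / n_tests`.
#'
#' `n_tests` defaults to the number of in-window variants in the
#' supplied data (the data-size-dependent reading of the multiple-
#' testing rule); pass a constant to reproduce an external analysis
#' count.
#'
#' @param records A `variant_counts` data.frame from
#'   [read_variant_counts()] or [sim_bottleneck_counts()].
#' @param study_pop Study population label (e.g. `"AJ"`).
#' @param reference_pops Character vector of reference population
#'   labels (e.g. `c("NFE", "AFR", "AMR")`).
#' @param af_window Study-frequency window `[low, high)`; default
#'   `c(0.002, 0.1)`.
#' @param alpha Family-wise error rate for the Bonferroni rule
#'   (default 0.05).
#' @param n_tests Bonferroni denominator; default `NULL` = number of
#'   in-window variants.
#' @param ref_af_min Minimum reference allele frequency for a
#'   population to be eligible as comparator (default 1e-4).
#' @return data.frame of class `enrichment_result` with one row per
#'   variant: `key, annotation, reference_pop, study_af, max_ref_af,
#'   beta_hat, se, odds_ratio, p_one_sided, in_window, enriched`.
#'   Variants with no eligible reference population have `NA`
#'   statistics and `enriched = FALSE`. Attributes `n_tests` and
#'   `n_in_window` record the multiple-testing bookkeeping.
#' @export
classify_enrichment <- function(records, study_pop, reference_pops,
                                af_window = c(0.002, 0.1), alpha = 0.05,
                                n_tests = NULL, ref_af_min = 1e-4) {
  ac_s <- records[[paste0("ac_", study_pop)]]
  an_s <- records[[paste0("an_", study_pop)]]
  if (is.null(ac_s) || is.null(an_s))
    stop("study population counts not present: ", study_pop)
  nv <- nrow(records)
  ref_af <- matrix(NA_real_, nv, length(reference_pops),
                   dimnames = list(NULL, reference_pops))
  ref_an <- ref_af
  for (p in reference_pops) {
    ac <- records[[paste0("ac_", p)]]
    an <- records[[paste0("an_", p)]]
    if (is.null(ac) || is.null(an))
      stop("reference population counts not present: ", p)
    cov_ok <- records[[paste0("coverage_ok_", p)]]
    if (is.null(cov_ok)) cov_ok <- rep(TRUE, nv)
    af <- ac / an
    eligible <- cov_ok & !is.na(af) & af >= ref_af_min
    ref_af[eligible, p] <- af[eligible]
    ref_an[eligible, p] <- an[eligible]
  }
  # argmax frequency; ties broken by larger AN then lexicographic label
  pick <- rep(NA_integer_, nv)
  any_ok <- rowSums(!is.na(ref_af)) > 0
  ord_cols <- order(colnames(ref_af))
  for (i in which(any_ok)) {
    afs <- ref_af[i, ]
    best <- which(afs == max(afs, na.rm = TRUE))
    if (length(best) > 1) {
      best <- best[ref_an[i, best] == max(ref_an[i, best])]
      if (length(best) > 1) best <- best[order(colnames(ref_af)[best])][1]
    }
    pick[i] <- best[1]
  }
  study_af <- ac_s / an_s
  max_ref_af <- ifelse(any_ok, ref_af[cbind(seq_len(nv), pick)], NA_real_)
  ref_pop <- ifelse(any_ok, colnames(ref_af)[pick], NA_character_)
  alt_r <- ref_s <- ref_r <- rep(NA_real_, nv)
  for (p in reference_pops) {
    sel <- which(ref_pop == p)
    alt_r[sel] <- records[[paste0("ac_", p)]][sel]
    ref_r[sel] <- records[[paste0("an_", p)]][sel] - alt_r[sel]
  }
  ref_s <- an_s - ac_s
  beta_hat <- se <- p1 <- rep(NA_real_, nv)
  ok <- which(any_ok)
  if (length(ok)) {
    b <- bias_corrected_log_or(ac_s[ok], ref_s[ok], alt_r[ok], ref_r[ok])
    beta_hat[ok] <- b$beta_hat
    se[ok] <- b$se
    p1[ok] <- fisher_one_sided(ac_s[ok], ref_s[ok], alt_r[ok], ref_r[ok])
  }
  in_window <- !is.na(study_af) &
    study_af >= af_window[1] & study_af < af_window[2]
  n_in_window <- sum(in_window)
  if (is.null(n_tests)) n_tests <- max(n_in_window, 1L)
  enriched <- in_window & !is.na(p1) & p1 < alpha / n_tests
  out <- data.frame(key = records$key,
                    annotation = records$annotation,
                    reference_pop = ref_pop,
                    study_af = study_af,
                    max_ref_af = max_ref_af,
                    beta_hat = beta_hat, se = se,
                    odds_ratio = exp(beta_hat),
                    p_one_sided = p1,
                    in_window = in_window,
                    enriched = enriched,
                    stringsAsFactors = FALSE)
  structure(out, n_tests = n_tests, n_in_window = n_in_window,
            alpha = alpha,
            class = c("enrichment_result", "data.frame"))
}

#' Enriched fraction by annotation class, with two-proportion tests
#'
#' Summarizes the fraction of in-window variants classified enriched
#' for every annotation class (plus `ALL`), and tests each functional
#' class against the synonymous baseline with a pooled-variance
#' two-proportion z test.
#'
#' @param results An `enrichment_result` data.frame.
#' @param baseline_class Class used as comparison baseline (default
#'   `"SYN"`).
#' @return List with `proportions` (data.frame `class, n_in_window,
#'   n_enriched, fraction`) and `tests` (data.frame `class, z, p` for
#'   each non-baseline class vs the baseline).
#' @export
annotation_class_proportions <- function(results, baseline_class = "SYN") {
  inw <- results[results$in_window, , drop = FALSE]
  classes <- intersect(ANNOTATION_CLASSES, unique(inw$annotation))
  tab <- data.frame(class = c("ALL", classes), stringsAsFactors = FALSE)
  tab$n_in_window <- c(nrow(inw), vapply(classes, function(cl)
    sum(inw$annotation == cl), 0L))
  tab$n_enriched <- c(sum(inw$enriched), vapply(classes, function(cl)
    sum(inw$enriched[inw$annotation == cl]), 0L))
  tab$fraction <- tab$n_enriched / tab$n_in_window
  empty <- tab$n_in_window == 0
  if (any(empty)) {
    warning("annotation class(es) with no in-window variants skipped: ",
            paste(tab$class[empty], collapse = ", "))
    tab <- tab[!empty, , drop = FALSE]
  }
  tests <- NULL
  if (baseline_class %in% tab$class) {
    b <- tab[tab$class == baseline_class, ]
    other <- tab[!(tab$class %in% c("ALL", baseline_class)), , drop = FALSE]
    if (nrow(other)) {
      z <- p <- numeric(nrow(other))
      for (i in seq_len(nrow(other))) {
        zt <- two_proportion_z(other$n_enriched[i], other$n_in_window[i],
                               b$n_enriched, b$n_in_window)
        z[i] <- zt$z; p[i] <- zt$p
      }
      tests <- data.frame(class = other$class, z = z, p = p,
                          stringsAsFactors = FALSE)
    }
  }
  list(proportions = tab, tests = tests)
}

# Pooled two-proportion z test (two-sided).
two_proportion_z <- function(x1, n1, x2, n2) {
  p1 <- x1 / n1; p2 <- x2 / n2
  pp <- (x1 + x2) / (n1 + n2)
  z <- (p1 - p2) / sqrt(pp * (1 - pp) * (1 / n1 + 1 / n2))
  if (p1 == p2) z <- 0  # includes the degenerate pp in {0,1} case
  list(z = z, p = 2 * stats::pnorm(-abs(z)))
}

#' Intersect enrichment results with a pathogenic-variant table
#'
#' Returns the enriched-direction variants whose key matches a
#' pathogenic, non-conflicted entry (at least one Pathogenic/Likely
#' pathogenic assertion and no Benign/Likely benign conflict) and whose
#' one-sided enrichment p-value is strictly below `p_cut`.
#'
#' @param results An `enrichment_result` data.frame.
#' @param pathogenic data.frame from [read_pathogenic_table()] (must be
#'   unique on key; a `conflicted` logical column marks conflicting
#'   assertions).
#' @param p_cut Strict p-value cutoff (default 0.005).
#' @return Subset of `results` rows matching the criteria, with the
#'   pathogenic table's `clinical_significance` column appended.
#' @export
intersect_pathogenic <- function(results, pathogenic, p_cut = 0.005) {
  if (anyDuplicated(pathogenic$key))
    stop("pathogenic table contains duplicate keys; de-duplicate on ",
         "chrom,pos,ref,alt first")
  eligible <- pathogenic[!pathogenic$conflicted, , drop = FALSE]
  hit <- results$key %in% eligible$key &
    !is.na(results$p_one_sided) & results$p_one_sided < p_cut
  out <- results[hit, , drop = FALSE]
  out$clinical_significance <-
    eligible$clinical_significance[match(out$key, eligible$key)]
  out
}

#' Recessive-risk enrichment implied by allele-frequency enrichment
#'
#' Under Hardy-Weinberg equilibrium the homozygote frequency scales
#' with the square of the allele frequency, so a k-fold allele
#' enrichment implies a k-squared-fold enrichment of recessive genetic
#' risk (e.g. a 19-fold enriched allele gives a 361-fold homozygote
#' enrichment).
#'
#' @param fold_enrichment Positive allele-frequency ratio between the
#'   two populations.
#' @return `fold_enrichment^2`. Vectorized.
#' @export
recessive_risk_enrichment <- function(fold_enrichment) {
  if (any(fold_enrichment <= 0))
    stop("fold_enrichment must be positive")
  fold_enrichment^2
}

#' Mean fold-enrichment of the enriched set
#'
#' Arithmetic (default) or geometric mean of the enrichment odds ratio
#' over variants classified enriched.
#'
#' @param results An `enrichment_result` data.frame.
#' @param type `"arithmetic"` or `"geometric"`.
#' @return Scalar mean odds ratio (NA if nothing is enriched).
#' @export
mean_fold_enrichment <- function(results,
                                 type = c("arithmetic", "geometric")) {
  type <- match.arg(type)
  or <- results$odds_ratio[results$enriched]
  if (!length(or)) return(NA_real_)
  if (type == "arithmetic") mean(or) else exp(mean(log(or)))
}
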