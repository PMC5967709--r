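#' Composite-carrier hit classes across a risk-variant set
#'
#' Counts risk alleles per sample across a gene's risk-variant set and
#' assigns the composite-carrier class: `0` (non-carrier), `1` (one
#' risk allele) or `2` (two or more — compound heterozygotes and, by
#' default, homozygotes for a single variant). Samples with missing
#' calls inside the set are classed on their observed variants and
#' flagged.
#'
#' @param matrix A `genotype_matrix`.
#' @param variant_set Character vector of variant keys in the set.
#' @param carriers_only If `TRUE`, each variant contributes at most one
#'   hit (dosage treated as presence/absence), so a homozygote for a
#'   single variant counts as 1 hit. Default `FALSE` (dosage counted,
#'   homozygote = 2 hits).
#' @return data.frame with `sample_id`, `hits` (integer allele count,
#'   capped at 2), `class` (factor "0"/"1"/"2+") and `incomplete`
#'   (TRUE if any set variant was missing for the sample).
#' @export
composite_carrier_coding <- function(matrix, variant_set,
                                     carriers_only = FALSE) {
  idx <- match(variant_set, matrix$variant_keys)
  if (anyNA(idx))
    stop("variant not present in genotype matrix: ",
         variant_set[is.na(idx)][1])
  g <- matrix$dosages[, idx, drop = FALSE]
  if (carriers_only) g <- (g > 0) * 1
  hits <- round(rowSums(g, na.rm = TRUE))
  incomplete <- rowSums(is.na(g)) > 0
  cls <- cut(pmin(hits, 2), breaks = c(-0.5, 0.5, 1.5, 2.5),
             labels = c("0", "1", "2+"))
  data.frame(sample_id = matrix$sample_ids, hits = as.integer(hits),
             class = cls, incomplete = incomplete,
             stringsAsFactors = FALSE)
}

#' 1-hit / 2-hit odds ratio model
#'
#' Estimates the odds ratio of disease for carriers of exactly one risk
#' allele (1-hit) and of two or more risk alleles (2-hit) relative to
#' non-carriers, from the 3x2 class-by-phenotype table. Confidence
#' intervals are Woolf intervals (log-OR +/- 1.96 * sqrt of summed
#' reciprocal cell counts). Under log-additivity the 2-hit odds ratio
#' would equal the square of the 1-hit odds ratio; the ratio of the
#' observed 2-hit OR to that prediction is reported as `deviation_or`,
#' with a penalized-likelihood-ratio p-value for the deviation.
#'
#' Zero cells receive the Haldane 0.5 correction (flagged).
#'
#' @param classes data.frame from [composite_carrier_coding()] (or any
#'   with a `class` column of levels "0"/"1"/"2+").
#' @param phenotype Binary 0/1 vector aligned with `classes`.
#' @return List of class `hit_model` with `or_1hit`, `ci_1hit`,
#'   `or_2hit`, `ci_2hit`, `additive_prediction` (= or_1hit^2),
#'   `deviation_or`, `deviation_p`, `table`, `haldane_corrected`,
#'   `has_2hit`.
#' @export
hit_model_fit <- function(classes, phenotype) {
  cls <- as.character(classes$class)
  if (length(phenotype) != length(cls))
    stop("phenotype length must match classes")
  tab <- table(factor(cls, levels = c("0", "1", "2+")),
               factor(phenotype, levels = c(0, 1)))
  cases <- tab[, "1"]; controls <- tab[, "0"]
  has_2hit <- (cases["2+"] + controls["2+"]) > 0
  if (cases["0"] + controls["0"] == 0)
    stop("no samples in the non-carrier reference class")

  or_ci <- function(a, b, c, d) {
    # a = cases_k, b = controls_k, c = cases_0, d = controls_0
    hald <- any(c(a, b, c, d) == 0)
    if (hald) { a <- a + 0.5; b <- b + 0.5; c <- c + 0.5; d <- d + 0.5 }
    lor <- log(a * d / (b * c))
    se <- sqrt(1 / a + 1 / b + 1 / c + 1 / d)
    list(or = exp(lor), ci = exp(lor + c(-1, 1) * 1.96 * se),
         haldane = hald)
  }
  e1 <- or_ci(cases["1"], controls["1"], cases["0"], controls["0"])
  res <- list(or_1hit = unname(e1$or), ci_1hit = unname(e1$ci),
              additive_prediction = unname(e1$or^2),
              table = tab, haldane_corrected = e1$haldane,
              has_2hit = has_2hit)
  if (has_2hit) {
    e2 <- or_ci(cases["2+"], controls["2+"], cases["0"], controls["0"])
    res$or_2hit <- unname(e2$or)
    res$ci_2hit <- unname(e2$ci)
    res$deviation_or <- unname(e2$or / e1$or^2)
    res$haldane_corrected <- res$haldane_corrected || e2$haldane
    # LRT: free 1-hit/2-hit terms vs the log-additive constraint
    y <- as.numeric(phenotype)
    d1 <- as.numeric(cls == "1"); d2 <- as.numeric(cls == "2+")
    X <- cbind(1, d1, d2)
    ll_free <- firth_glm(X, y)$loglik
    # log-additive constraint beta_2hit = 2 beta_1hit, same penalty
    ll_add <- firth_glm(X, y,
                        coef_map = rbind(c(1, 0), c(0, 1), c(0, 2)))$loglik
    lrt <- max(0, 2 * (ll_free - ll_add))
    res$deviation_p <- stats::pchisq(lrt, df = 1, lower.tail = FALSE)
  } else {
    res$or_2hit <- res$ci_2hit <- res$deviation_or <- res$deviation_p <- NA
    warning("no 2-hit carriers observed; 2-hit fields unavailable")
  }
  class(res) <- "hit_model"
  res
}

#' Test for deviation from log-additivity
#'
#' Within-gene mode (only `set_a` given): classes 0/1/2+ are built from
#' `set_a` and the free logistic model with separate 1-hit and 2-hit
#' terms is compared against the log-additive constraint
#' (beta_2hit = 2 * beta_1hit) by a penalized-likelihood-ratio test
#' (1 df). Between-gene mode (`set_b` given): carrier indicators for
#' each set enter a logistic model with and without an interaction
#' term; the null of no interaction corresponds to the two genes'
#' effects summing on the log-odds scale.
#'
#' Firth penalization guards the sparse 2-hit / double-carrier cells.
#'
#' @param matrix A `genotype_matrix` (its `phenotype` is the outcome).
#' @param set_a Character vector of risk-variant keys.
#' @param set_b Optional second gene's risk-variant keys.
#' @param carriers_only Passed to [composite_carrier_coding()].
#' @return List with `p` (LRT p-value), `lrt`, `df`, `mode`, and the
#'   free-model coefficient estimates.
#' @export
additivity_deviation_test <- function(matrix, set_a, set_b = NULL,
                                      carriers_only = FALSE) {
  y <- as.numeric(matrix$phenotype)
  if (is.null(set_b)) {
    cc <- composite_carrier_coding(matrix, set_a, carriers_only)
    cls <- as.character(cc$class)
    counts <- table(factor(cls, levels = c("0", "1", "2+")))
    if (any(counts == 0))
      stop("empty hit class: ", names(counts)[counts == 0][1])
    d1 <- as.numeric(cls == "1"); d2 <- as.numeric(cls == "2+")
    X <- cbind(1, d1, d2)
    free <- firth_glm(X, y)
    constrained <- firth_glm(X, y,
                             coef_map = rbind(c(1, 0), c(0, 1), c(0, 2)))
    est <- c(beta_1hit = unname(free$beta[2]),
             beta_2hit = unname(free$beta[3]))
    mode <- "within-gene"
  } else {
    a <- composite_carrier_coding(matrix, set_a, carriers_only)$hits > 0
    b <- composite_carrier_coding(matrix, set_b, carriers_only)$hits > 0
    a <- as.numeric(a); b <- as.numeric(b)
    if (sum(a * b) == 0)
      stop("empty hit class: no double carriers of both sets")
    X <- cbind(1, a, b, a * b)
    free <- firth_glm(X, y)
    constrained <- firth_glm(X, y,
                             coef_map = rbind(c(1, 0, 0), c(0, 1, 0),
                                              c(0, 0, 1), c(0, 0, 0)))
    est <- c(beta_a = unname(free$beta[2]), beta_b = unname(free$beta[3]),
             interaction = unname(free$beta[4]))
    mode <- "between-gene"
  }
  lrt <- max(0, 2 * (free$loglik - constrained$loglik))
  list(p = stats::pchisq(lrt, df = 1, lower.tail = FALSE),
       lrt = lrt, df = 1L, mode = mode, estimates = est)
}
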