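#' Build an effect table for PRS and liability modelling
#'
#' Validates a per-variant table of effect sizes and per-population
#' frequencies: column `key`, additive log odds ratio `beta`
#' (optionally genotype-specific `beta_het`/`beta_hom` — both or
#' neither), and one `freq_<pop>` column per population, values in
#' [0, 1]. Effect alleles are the alt alleles of the keys.
#'
#' @param x data.frame with the columns above.
#' @return `x` with class `effect_table` and attribute `populations`.
#' @export
effect_table <- function(x) {
  if (!"key" %in% names(x)) stop("effect table requires a 'key' column")
  if (!"beta" %in% names(x)) stop("effect table requires a 'beta' column")
  has_het <- "beta_het" %in% names(x)
  has_hom <- "beta_hom" %in% names(x)
  if (has_het != has_hom)
    stop("beta_het and beta_hom must be supplied together")
  fcols <- grep("^freq_", names(x), value = TRUE)
  for (fc in fcols) {
    f <- x[[fc]]
    if (any(!is.na(f) & (f < 0 | f > 1)))
      stop("frequencies must lie in [0, 1]: column ", fc)
  }
  structure(as.data.frame(x), populations = sub("^freq_", "", fcols),
            class = c("effect_table", "data.frame"))
}

effect_freq <- function(effects, population) {
  fc <- paste0("freq_", population)
  f <- effects[[fc]]
  if (is.null(f))
    stop("no frequencies for population: ", population)
  if (anyNA(f))
    stop("missing frequency for variant ", effects$key[is.na(f)][1],
         " in population ", population)
  f
}

#' Individual polygenic risk scores
#'
#' Computes `PRS_i = sum_m beta_m * G_im` over the effect-table
#' variants, assuming additive effects on the log-odds scale. A missing
#' dosage is replaced by its imputed expected value `2 * f` using the
#' frequency column named by `impute_population`; if no frequency is
#' available for a variant with missing calls, an error names it.
#'
#' @param matrix A `genotype_matrix`.
#' @param effects An `effect_table`; variants absent from the matrix
#'   cause an error.
#' @param impute_population Population label whose `freq_<pop>` column
#'   supplies imputation frequencies (default: first available).
#' @param exclude Optional character vector of variant keys excluded
#'   from the score (e.g. genes modelled separately).
#' @return Numeric vector of scores named by sample id.
#' @export
compute_prs <- function(matrix, effects, impute_population = NULL,
                        exclude = NULL) {
  eff <- effects
  if (!is.null(exclude)) eff <- eff[!(eff$key %in% exclude), , drop = FALSE]
  idx <- match(eff$key, matrix$variant_keys)
  if (anyNA(idx))
    stop("effect variant not present in genotype matrix: ",
         eff$key[is.na(idx)][1])
  g <- matrix$dosages[, idx, drop = FALSE]
  if (anyNA(g)) {
    pops <- attr(effects, "populations")
    if (is.null(impute_population)) {
      if (!length(pops))
        stop("missing dosages present but effect table has no ",
             "frequency column for imputation")
      impute_population <- pops[1]
    }
    f <- effect_freq(eff, impute_population)
    miss_var <- which(colSums(is.na(g)) > 0)
    for (j in miss_var) {
      if (is.na(f[j]))
        stop("missing dosage and no imputation frequency for variant ",
             eff$key[j])
      g[is.na(g[, j]), j] <- 2 * f[j]
    }
  }
  scores <- drop(g %*% eff$beta)
  names(scores) <- matrix$sample_ids
  scores
}

#' Expected polygenic risk score in a population
#'
#' Closed form under Hardy-Weinberg equilibrium:
#' `E[PRS]_j = sum_m 2 * beta_m * f_mj`.
#'
#' @param effects An `effect_table`.
#' @param population Population label (selects `freq_<pop>`).
#' @param exclude Optional variant keys to exclude.
#' @return Scalar expected score.
#' @export
expected_prs <- function(effects, population, exclude = NULL) {
  eff <- effects
  if (!is.null(exclude)) eff <- eff[!(eff$key %in% exclude), , drop = FALSE]
  f <- effect_freq(eff, population)
  sum(2 * eff$beta * f)
}

#' Expected between-population PRS difference, decomposed by variant
#'
#' `E[Diff] = sum_m 2 * beta_m * (f_m,a - f_m,b)`; each variant's
#' contribution `2 * beta_m * (f_m,a - f_m,b)` is returned ranked in
#' decreasing order, with highlight flags at `|contribution| >=
#' highlight_cut` (default 0.01) separately for the positive and
#' negative directions.
#'
#' @param effects An `effect_table`.
#' @param pop_a,pop_b Population labels (difference is a minus b).
#' @param highlight_cut Absolute contribution flag threshold.
#' @param exclude Optional variant keys to exclude.
#' @return List with `total` and `contributions` (data.frame `key,
#'   contribution, highlight` in decreasing contribution order;
#'   highlight is "up", "down" or "").
#' @export
expected_prs_difference <- function(effects, pop_a, pop_b,
                                    highlight_cut = 0.01, exclude = NULL) {
  eff <- effects
  if (!is.null(exclude)) eff <- eff[!(eff$key %in% exclude), , drop = FALSE]
  fa <- effect_freq(eff, pop_a)
  fb <- effect_freq(eff, pop_b)
  contrib <- 2 * eff$beta * (fa - fb)
  ord <- order(contrib, decreasing = TRUE)
  hl <- ifelse(contrib >= highlight_cut, "up",
               ifelse(contrib <= -highlight_cut, "down", ""))
  list(total = sum(contrib),
       contributions = data.frame(key = eff$key[ord],
                                  contribution = contrib[ord],
                                  highlight = hl[ord],
                                  stringsAsFactors = FALSE))
}

#' Expected PRS under genotype-specific (non-additive) effects
#'
#' `E[PRS*]_j = sum_m [2 f (1 - f) beta_het + f^2 beta_hom]` with
#' genotype frequencies at Hardy-Weinberg equilibrium. Reduces exactly
#' to the additive [expected_prs()] whenever `beta_hom = 2 * beta_het`.
#'
#' @inheritParams expected_prs
#' @return Scalar expected score.
#' @export
expected_prs_nonadditive <- function(effects, population, exclude = NULL) {
  eff <- effects
  if (!is.null(exclude)) eff <- eff[!(eff$key %in% exclude), , drop = FALSE]
  if (!all(c("beta_het", "beta_hom") %in% names(eff)))
    stop("effect table lacks beta_het/beta_hom columns")
  if (anyNA(eff$beta_het) || anyNA(eff$beta_hom))
    stop("beta_het and beta_hom must be fully specified")
  f <- effect_freq(eff, population)
  sum(2 * f * (1 - f) * eff$beta_het + f^2 * eff$beta_hom)
}

#' Standardize scores to a reference control group
#'
#' Transforms all scores by `(x - mean_ref) / sd_ref` so the reference
#' subset has mean 0 and variance 1, and reports the mean of each
#' non-reference group on that scale (the between-group shift in
#' reference standard-deviation units).
#'
#' @param scores Numeric vector of per-sample scores.
#' @param reference Logical or index vector selecting the reference
#'   subset (size >= 2, non-zero variance).
#' @param group Optional vector of group labels used to report
#'   per-group shifts; default: reference vs non-reference.
#' @return List with `standardized` (transformed scores), `shift`
#'   (named mean per non-reference group), `mean_ref`, `sd_ref`.
#' @export
standardize_scores <- function(scores, reference, group = NULL) {
  ref <- scores[reference]
  if (length(ref) < 2) stop("reference subset must have >= 2 samples")
  m <- mean(ref)
  s <- stats::sd(ref)
  if (s == 0) stop("reference subset has zero variance")
  std <- (scores - m) / s
  if (is.null(group)) {
    is_ref <- logical(length(scores))
    is_ref[reference] <- TRUE
    shift <- c(nonreference = mean(std[!is_ref]))
  } else {
    shift <- tapply(std, group, mean)
  }
  list(standardized = std, shift = shift, mean_ref = m, sd_ref = s)
}
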