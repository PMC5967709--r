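#' Assign a sample to an ancestry group from admixture fractions
#'
#' A sample is assigned to group *k* iff its estimated ancestry fraction
#' for *k* is at least `threshold` and every other fraction is strictly
#' below `threshold`; otherwise it is `"admixed"`. With the default
#' threshold of 0.4 at K = 4 at most one group can qualify unless two
#' fractions tie at >= 0.4, which is admixed by the "remaining fractions
#' < threshold" clause.
#'
#' @param fractions Numeric matrix or data.frame of ancestry fractions
#'   (samples in rows, K >= 2 groups in columns, rows summing to 1), or
#'   a single numeric vector for one sample.
#' @param threshold Assignment threshold (default 0.4).
#' @return Character vector of group labels (column names, or
#'   `"group<k>"`) with `"admixed"` where no single group dominates.
#' @export
assign_ancestry <- function(fractions, threshold = 0.4) {
  q <- as.matrix(if (is.null(dim(fractions))) t(fractions) else fractions)
  if (ncol(q) < 2) stop("at least K = 2 ancestry fractions required")
  if (any(q < 0)) stop("ancestry fractions must be non-negative")
  if (any(abs(rowSums(q) - 1) > 1e-6))
    stop("ancestry fractions must sum to 1 per sample")
  labels <- colnames(q)
  if (is.null(labels)) labels <- paste0("group", seq_len(ncol(q)))
  n_ge <- rowSums(q >= threshold)
  top <- max.col(q, ties.method = "first")
  out <- ifelse(n_ge == 1, labels[top], "admixed")
  names(out) <- rownames(q)
  out
}

#' Flag samples with high ancestry fraction in a target group
#'
#' Strict-inequality rule used to build a low-admixture frequency panel:
#' a sample qualifies iff its fraction for `target_group` exceeds
#' `threshold` (default 0.9; exactly 0.9 does not qualify).
#'
#' @inheritParams assign_ancestry
#' @param target_group Column label (or index) of the focal group.
#' @param threshold High-ancestry cutoff, strict (default 0.9).
#' @return Logical vector, one element per sample.
#' @export
flag_high_ancestry <- function(fractions, target_group, threshold = 0.9) {
  q <- as.matrix(if (is.null(dim(fractions))) t(fractions) else fractions)
  if (is.character(target_group)) {
    if (!target_group %in% colnames(q))
      stop("unknown ancestry group: ", target_group)
    target_group <- match(target_group, colnames(q))
  } else if (target_group < 1 || target_group > ncol(q))
    stop("unknown ancestry group index: ", target_group)
  out <- q[, target_group] > threshold
  names(out) <- rownames(q)
  out
}

#' Sample-level quality-control filter
#'
#' Excludes samples failing any of the standard exome QC rules:
#' heterozygous/homozygous ratio below 1 (possible contamination),
#' singleton excess (> 2000), deletion/insertion ratio above 1.5, or
#' mean genotype quality below 40. Each exclusion carries the list of
#' rules failed.
#'
#' @param metrics data.frame with columns `sample_id, het_hom_ratio,
#'   n_singletons, del_ins_ratio, mean_gq` (a `call_rate` column may be
#'   present and is passed through).
#' @param thresholds Named list overriding the defaults
#'   `list(het_hom_min = 1, singletons_max = 2000, del_ins_max = 1.5,
#'   mean_gq_min = 40)`.
#' @return List with `kept` (character sample ids) and `excluded`
#'   (data.frame of `sample_id`, `reasons` — ';'-joined failed rules).
#' @export
sample_qc_filter <- function(metrics, thresholds = list()) {
  th <- utils::modifyList(list(het_hom_min = 1, singletons_max = 2000,
                               del_ins_max = 1.5, mean_gq_min = 40),
                          thresholds)
  need <- c("sample_id", "het_hom_ratio", "n_singletons",
            "del_ins_ratio", "mean_gq")
  miss <- setdiff(need, names(metrics))
  if (length(miss)) stop("metrics missing column(s): ",
                         paste(miss, collapse = ", "))
  for (f in need[-1]) {
    if (anyNA(metrics[[f]]))
      stop("missing metric '", f, "' for sample ",
           metrics$sample_id[is.na(metrics[[f]])][1])
  }
  reasons <- lapply(seq_len(nrow(metrics)), function(i) {
    r <- character()
    if (metrics$het_hom_ratio[i] < th$het_hom_min)
      r <- c(r, sprintf("het_hom_ratio<%g", th$het_hom_min))
    if (metrics$n_singletons[i] > th$singletons_max)
      r <- c(r, sprintf("n_singletons>%g", th$singletons_max))
    if (metrics$del_ins_ratio[i] > th$del_ins_max)
      r <- c(r, sprintf("del_ins_ratio>%g", th$del_ins_max))
    if (metrics$mean_gq[i] < th$mean_gq_min)
      r <- c(r, sprintf("mean_gq<%g", th$mean_gq_min))
    r
  })
  fail <- lengths(reasons) > 0
  list(kept = as.character(metrics$sample_id[!fail]),
       excluded = data.frame(
         sample_id = as.character(metrics$sample_id[fail]),
         reasons = vapply(reasons[fail], paste, "", collapse = ";"),
         stringsAsFactors = FALSE))
}

#' Variant-level quality-control filter
#'
#' Excludes a variant if its call rate is below 0.8, or if at least 7
#' heterozygous samples were observed and more than 40% of them have
#' allele balance deviating from the 70:30 rule (heterozygote ALT read
#' fraction outside [0.3, 0.7]; the boundary passes). Below 7
#' heterozygotes the allele-balance rule is inactive.
#'
#' @param variants data.frame with columns `key, call_rate, n_het,
#'   n_ab_deviating`.
#' @param call_rate_min Minimum call rate (default 0.8).
#' @param ab_fraction_max Maximum tolerated deviating fraction, strict
#'   (default 0.4).
#' @param ab_min_het Minimum heterozygote count activating the
#'   allele-balance rule (default 7).
#' @return List with `kept` (character keys) and `excluded` (data.frame
#'   `key`, `reasons`).
#' @export
variant_qc_filter <- function(variants, call_rate_min = 0.8,
                              ab_fraction_max = 0.4, ab_min_het = 7) {
  if (any(variants$n_ab_deviating > variants$n_het))
    stop("n_ab_deviating cannot exceed n_het")
  low_cr <- variants$call_rate < call_rate_min
  ab_bad <- variants$n_het >= ab_min_het &
    variants$n_ab_deviating / variants$n_het > ab_fraction_max
  reasons <- mapply(function(cr, ab) {
    r <- character()
    if (cr) r <- c(r, sprintf("call_rate<%g", call_rate_min))
    if (ab) r <- c(r, sprintf("allele_balance_deviating>%g", ab_fraction_max))
    paste(r, collapse = ";")
  }, low_cr, ab_bad)
  fail <- low_cr | ab_bad
  list(kept = as.character(variants$key[!fail]),
       excluded = data.frame(key = as.character(variants$key[fail]),
                             reasons = reasons[fail],
                             stringsAsFactors = FALSE))
}

#' Relatedness pruning
#'
#' Removes samples until no remaining pair exceeds the relatedness
#' cutoff (default 0.35). For small above-cutoff graphs (up to
#' `exact_limit` involved samples) the exclusion set is an exact
#' minimum vertex cover found by branch and bound, chosen
#' deterministically among minimum covers; larger graphs fall back to
#' a greedy rule (repeatedly exclude
#' the sample in the most above-cutoff pairs, ties broken by lower
#' call rate then lexicographic id).
#'
#' @param pairs data.frame with columns `id1, id2, relatedness`
#'   (symmetric; each unordered pair listed once).
#' @param cutoff Relatedness cutoff, strict (default 0.35).
#' @param call_rate Optional named numeric vector of per-sample call
#'   rates used for greedy tie-breaking (lower call rate excluded
#'   first).
#' @param exact_limit Maximum number of involved samples for the exact
#'   minimum cover (default 25).
#' @return Character vector of excluded sample ids (possibly empty).
#' @export
relatedness_prune <- function(pairs, cutoff = 0.35, call_rate = NULL,
                              exact_limit = 25) {
  act <- pairs[pairs$relatedness > cutoff, , drop = FALSE]
  if (nrow(act) == 0) return(character())
  edges <- cbind(as.character(act$id1), as.character(act$id2))
  ids <- unique(c(edges))
  if (length(ids) <= exact_limit)
    return(min_vertex_cover(edges))
  excluded <- character()
  while (nrow(act) > 0) {
    all_ids <- c(as.character(act$id1), as.character(act$id2))
    deg <- table(all_ids)
    cand <- names(deg)[deg == max(deg)]
    if (length(cand) > 1 && !is.null(call_rate)) {
      cr <- call_rate[cand]
      cr[is.na(cr)] <- Inf
      cand <- cand[cr == min(cr)]
    }
    drop <- sort(cand)[1]
    excluded <- c(excluded, drop)
    act <- act[act$id1 != drop & act$id2 != drop, , drop = FALSE]
  }
  sort(excluded)
}

# Exact minimum vertex cover by branch and bound on an edge (u, v):
# every cover contains u or v. Returns the lexicographically smallest
# among minimum covers for determinism.
min_vertex_cover <- function(edges) {
  better <- function(a, b) {
    if (is.null(b)) return(TRUE)
    if (length(a) != length(b)) return(length(a) < length(b))
    cmp <- which(a != b)
    length(cmp) > 0 && a[cmp[1]] < b[cmp[1]]
  }
  recurse <- function(edges, chosen, best) {
    if (nrow(edges) == 0) {
      cand <- sort(chosen)
      return(if (better(cand, best)) cand else best)
    }
    if (!is.null(best) && length(chosen) >= length(best)) return(best)
    u <- edges[1, 1]; v <- edges[1, 2]
    for (pick in sort(c(u, v))) {
      keep <- edges[, 1] != pick & edges[, 2] != pick
      best <- recurse(edges[keep, , drop = FALSE], c(chosen, pick), best)
    }
    best
  }
  recurse(edges, character(), NULL)
}
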