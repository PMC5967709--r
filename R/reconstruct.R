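#' Reconstruct enrichment odds ratios from printed allele frequencies
#'
#' Given per-variant study and reference allele frequencies (as printed
#' in a summary table) and assumed total allele numbers, reconstructs
#' integer allele counts (`round(af * an)`) and re-applies the
#' bias-corrected log odds ratio. Useful to check a published
#' enrichment table when per-site allele numbers are unknown; agreement
#' is approximate because printed frequencies are rounded and real AN
#' varies by site with coverage.
#'
#' @param study_af,ref_af Allele-frequency vectors.
#' @param study_an,ref_an Assumed total allele numbers (scalars or
#'   vectors).
#' @return data.frame with the reconstructed counts, `beta_hat`, `se`
#'   and `odds_ratio`.
#' @export
enrichment_or_from_freqs <- function(study_af, ref_af, study_an, ref_an) {
  ac_s <- round(study_af * study_an)
  ac_r <- round(ref_af * ref_an)
  b <- bias_corrected_log_or(ac_s, study_an - ac_s, ac_r, ref_an - ac_r)
  data.frame(ac_study = ac_s, an_study = study_an,
             ac_ref = ac_r, an_ref = ref_an,
             beta_hat = b$beta_hat, se = b$se, odds_ratio = b$odds_ratio)
}

#' Bundled example: published founder-enriched pathogenic alleles
#'
#' Loads the packaged table of 48 ClinVar-pathogenic alleles enriched
#' in the Ashkenazi Jewish population (variant key, gene, published
#' enrichment odds ratio, study allele frequency, maximum reference
#' allele frequency), used by the worked examples and the
#' reconstruction checks.
#'
#' @return data.frame with columns `variant, gene, enrichment_or,
#'   study_af, max_ref_af`.
#' @export
aj_enriched_pathogenic_table <- function() {
  path <- system.file("extdata", "aj_enriched_clinvar_table1.tsv",
                      package = "founderisk", mustWork = TRUE)
  read_results(path)
}
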