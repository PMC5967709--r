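ANNOTATION_CLASSES <- c("PTV", "PRA", "SYN", "OTHER")

# Shared TSV dialect: tab-separated, single '#'-prefixed header line,
# UTF-8, '.' for missing values.
read_dialect_tsv <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  header <- readLines(path, n = 1L)
  has_hash <- startsWith(header, "#")
  if (has_hash) header <- sub("^#", "", header)
  cols <- strsplit(header, "\t", fixed = TRUE)[[1]]
  dat <- utils::read.table(path, sep = "\t", skip = 1L, header = FALSE,
                           col.names = cols, na.strings = ".",
                           colClasses = "character", quote = "",
                           comment.char = "", stringsAsFactors = FALSE,
                           fill = FALSE, encoding = "UTF-8",
                           check.names = FALSE)
  for (j in seq_along(dat)) {
    v <- dat[[j]]
    suppressWarnings(num <- as.numeric(v))
    if (!anyNA(num[!is.na(v)])) dat[[j]] <- num
  }
  dat
}

write_dialect_tsv <- function(dat, path, digits = 10) {
  out <- dat
  for (j in seq_along(out)) {
    v <- out[[j]]
    if (is.double(v)) v <- formatC(v, digits = digits, format = "g")
    v <- as.character(v)
    v[is.na(dat[[j]]) | v == "NA"] <- "."
    out[[j]] <- v
  }
  con <- file(path, open = "wt", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(paste0("#", paste(names(out), collapse = "\t")), con)
  if (nrow(out))
    utils::write.table(out, con, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read per-variant, per-population allele counts
#'
#' Reads a variant-count table (TSV, or VCF with `AC_<pop>`/`AN_<pop>`
#' INFO keys) into a validated `variant_counts` data.frame: one row per
#' biallelic variant, with allele counts (`ac_<pop>`), total allele
#' numbers (`an_<pop>`) and optional per-reference coverage flags
#' (`coverage_ok_<pop>`, the "at least 20X in at least 80% of samples"
#' site metadata supplied upstream).
#'
#' The TSV schema is `chrom, pos, ref, alt, annotation, AC_<pop>,
#' AN_<pop>[, coverage_ok_<pop>]` with a `#`-prefixed header.
#' Annotation classes are `PTV` (protein-truncating), `PRA`
#' (protein-altering), `SYN` (synonymous) or `OTHER`.
#'
#' @param path Path to the TSV (or `.vcf`) file.
#' @param population_spec Optional named character vector renaming
#'   population column suffixes, e.g. `c(ExAC = "NFE")` relabels
#'   `AC_ExAC` as population `NFE`.
#' @return A data.frame of class `variant_counts` with columns `key,
#'   chrom, pos, ref, alt, annotation` plus per-population `ac_*`,
#'   `an_*` and `coverage_ok_*` columns; attribute `"populations"`
#'   lists the population labels found.
#' @export
read_variant_counts <- function(path, population_spec = NULL) {
  if (grepl("\\.vcf(\\.gz)?$", path)) {
    dat <- read_counts_vcf(path)
  } else {
    dat <- read_dialect_tsv(path)
  }
  names(dat)[names(dat) == "AC"] <- "AC_"  # guard against bare names
  required <- c("chrom", "pos", "ref", "alt", "annotation")
  missing_cols <- setdiff(required, names(dat))
  if (length(missing_cols))
    stop("variant count table is missing required column(s): ",
         paste(missing_cols, collapse = ", "))
  ac_cols <- grep("^AC_", names(dat), value = TRUE)
  pops <- sub("^AC_", "", ac_cols)
  pops <- pops[nzchar(pops)]
  if (!length(pops))
    stop("variant count table is missing required column(s): AC_<pop>")
  an_missing <- setdiff(paste0("AN_", pops), names(dat))
  if (length(an_missing))
    stop("variant count table is missing required column(s): ",
         paste(an_missing, collapse = ", "))
  if (!is.null(population_spec)) {
    idx <- match(pops, names(population_spec))
    pops_new <- ifelse(is.na(idx), pops, unname(population_spec[idx]))
  } else pops_new <- pops

  key <- variant_key(dat$chrom, dat$pos, dat$ref, dat$alt)
  bad_ann <- !(dat$annotation %in% ANNOTATION_CLASSES)
  if (any(bad_ann))
    stop("unknown annotation class '", dat$annotation[bad_ann][1],
         "' at line ", which(bad_ann)[1] + 1L, " (", key[bad_ann][1], ")")
  out <- data.frame(key = key, chrom = as.character(dat$chrom),
                    pos = as.integer(dat$pos), ref = dat$ref, alt = dat$alt,
                    annotation = dat$annotation, stringsAsFactors = FALSE)
  for (i in seq_along(pops)) {
    ac <- as.numeric(dat[[paste0("AC_", pops[i])]])
    an <- as.numeric(dat[[paste0("AN_", pops[i])]])
    bad <- !is.na(ac) & !is.na(an) & (ac < 0 | an <= 0 | ac > an)
    if (any(bad))
      stop("invalid allele counts for population ", pops_new[i],
           " at line ", which(bad)[1] + 1L, ": AC=", ac[bad][1],
           " AN=", an[bad][1], " (", key[bad][1], ")")
    out[[paste0("ac_", pops_new[i])]] <- as.integer(ac)
    out[[paste0("an_", pops_new[i])]] <- as.integer(an)
    cov_col <- paste0("coverage_ok_", pops[i])
    if (cov_col %in% names(dat)) {
      out[[paste0("coverage_ok_", pops_new[i])]] <-
        as.logical(as.numeric(dat[[cov_col]]) != 0 |
                     dat[[cov_col]] %in% c("TRUE", "true", "T"))
    }
  }
  structure(out, populations = pops_new,
            class = c("variant_counts", "data.frame"))
}

read_counts_vcf <- function(path) {
  if (!requireNamespace("vcfR", quietly = TRUE))
    stop("reading VCF variant counts requires the 'vcfR' package")
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(vcfR::getFIX(v), stringsAsFactors = FALSE)
  info <- vcfR::getINFO(v)
  grab <- function(key) {
    hit <- regexpr(paste0("(^|;)", key, "=[^;]*"), info)
    val <- rep(NA_character_, length(info))
    ok <- hit > 0
    val[ok] <- sub(paste0("^;?", key, "="), "",
                   regmatches(info, hit)[seq_len(sum(ok))])
    val
  }
  keys <- unique(unlist(regmatches(
    info, gregexpr("(?<=^|;)[A-Za-z0-9_]+(?==)", info, perl = TRUE))))
  dat <- data.frame(chrom = fix$CHROM, pos = fix$POS, ref = fix$REF,
                    alt = fix$ALT, stringsAsFactors = FALSE)
  ann <- grab("ANN")
  dat$annotation <- ifelse(is.na(ann), "OTHER", ann)
  for (k in grep("^(AC|AN|coverage_ok)_", keys, value = TRUE))
    dat[[k]] <- grab(k)
  dat
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Construct a case-control genotype matrix
#'
#' Bundles a samples-by-variants dosage matrix with a binary phenotype,
#' numeric covariates (e.g. principal components) and a missingness
#' mask. Dosages are allele counts in `[0, 2]` (hard calls 0/1/2 or
#' imputed expected values); missing entries are `NA` in `dosages` and
#' `TRUE` in `missing_mask` — imputation is the caller's choice
#' downstream (PRS imputes `2f`, association drops incomplete samples
#' per variant).
#'
#' @param dosages Numeric matrix, samples in rows, variants in columns;
#'   column names are canonical variant keys.
#' @param phenotype Binary 0/1 vector, one element per sample.
#' @param covariates Optional numeric matrix of per-sample covariates.
#' @param sample_ids Optional sample identifiers (default from rownames).
#' @return An object of class `genotype_matrix`.
#' @export
genotype_matrix <- function(dosages, phenotype, covariates = NULL,
                            sample_ids = NULL) {
  dosages <- as.matrix(dosages)
  storage.mode(dosages) <- "double"
  if (is.null(sample_ids))
    sample_ids <- rownames(dosages) %||% paste0("S", seq_len(nrow(dosages)))
  if (length(phenotype) != nrow(dosages))
    stop("phenotype length must equal number of samples")
  if (!all(phenotype %in% c(0, 1)))
    stop("phenotype must be binary 0/1")
  rng <- range(dosages, na.rm = TRUE)
  if (is.finite(rng[1]) && (rng[1] < 0 || rng[2] > 2))
    stop("dosages must lie in [0, 2]; found ",
         if (rng[2] > 2) rng[2] else rng[1])
  if (!is.null(covariates)) {
    covariates <- as.matrix(covariates)
    if (nrow(covariates) != nrow(dosages))
      stop("covariates must have one row per sample")
  }
  structure(list(dosages = dosages,
                 sample_ids = as.character(sample_ids),
                 variant_keys = colnames(dosages),
                 phenotype = as.integer(phenotype),
                 covariates = covariates,
                 missing_mask = is.na(dosages)),
            class = "genotype_matrix")
}

#' Read a genotype dosage matrix with phenotype and covariates
#'
#' Reads a samples-as-rows dosage TSV (`sample_id` column followed by
#' one column per variant key) together with an optional sidecar TSV
#' keyed by `sample_id` holding the `phenotype` column and any numeric
#' covariates. If no sidecar is given the main table must contain a
#' `phenotype` column itself. Missing calls (`.`) are flagged in the
#' missingness mask, never silently imputed.
#'
#' @param path Path to the dosage TSV.
#' @param sidecar Optional path to the phenotype/covariate TSV.
#' @return A `genotype_matrix`.
#' @export
read_genotypes <- function(path, sidecar = NULL) {
  dat <- read_dialect_tsv(path)
  if (!"sample_id" %in% names(dat))
    stop("genotype table is missing required column: sample_id")
  ids <- as.character(dat$sample_id)
  if (!is.null(sidecar)) {
    side <- read_dialect_tsv(sidecar)
    if (!all(c("sample_id", "phenotype") %in% names(side)))
      stop("sidecar must contain sample_id and phenotype columns")
    idx <- match(ids, as.character(side$sample_id))
    if (anyNA(idx))
      stop("sample missing from sidecar: ", ids[is.na(idx)][1])
    phenotype <- side$phenotype[idx]
    cov_cols <- setdiff(names(side), c("sample_id", "phenotype"))
    covariates <- if (length(cov_cols))
      as.matrix(side[idx, cov_cols, drop = FALSE]) else NULL
    geno_cols <- setdiff(names(dat), "sample_id")
  } else {
    if (!"phenotype" %in% names(dat))
      stop("genotype table is missing required column: phenotype")
    phenotype <- dat$phenotype
    covariates <- NULL
    geno_cols <- setdiff(names(dat), c("sample_id", "phenotype"))
  }
  if (!all(phenotype %in% c(0, 1)))
    stop("phenotype must be binary 0/1")
  g <- as.matrix(dat[, geno_cols, drop = FALSE])
  storage.mode(g) <- "double"
  rownames(g) <- ids
  genotype_matrix(g, phenotype, covariates, sample_ids = ids)
}

#' Write a result table to TSV
#'
#' Serializes any flat result collection (data.frame) to the package's
#' TSV dialect: tab-separated, `#`-prefixed header, `.` for missing,
#' floats at fixed precision. Re-reading with [read_results()]
#' reproduces the values at the serialized precision. Column order is
#' preserved deterministically.
#'
#' @param records A data.frame (all rows share one schema).
#' @param path Output path.
#' @param digits Significant digits for floating-point columns.
#' @export
write_results <- function(records, path, digits = 10) {
  if (!is.data.frame(records)) {
    if (is.list(records)) {
      schemas <- unique(vapply(records, function(r)
        paste(names(r), collapse = ","), ""))
      if (length(schemas) > 1)
        stop("records do not share a common schema")
      records <- do.call(rbind, lapply(records, as.data.frame))
    } else stop("records must be a data.frame or list of records")
  }
  write_dialect_tsv(as.data.frame(records), path, digits = digits)
}

#' @rdname write_results
#' @return `read_results()` returns the table as a data.frame with
#'   numeric columns restored.
#' @export
read_results <- function(path) read_dialect_tsv(path)

#' Read a pathogenic-variant table (ClinVar flat-file style)
#'
#' Expects columns `chrom, pos, ref, alt, clinical_significance,
#' conflicted` (conflicted: 0/1 flag — at least one Pathogenic/Likely
#' pathogenic assertion together with at least one Benign/Likely benign
#' assertion). The table must be unique on chrom,pos,ref,alt.
#'
#' @param path Path to the TSV.
#' @return data.frame with a `key` column prepended.
#' @export
read_pathogenic_table <- function(path) {
  dat <- read_dialect_tsv(path)
  need <- c("chrom", "pos", "ref", "alt", "clinical_significance", "conflicted")
  miss <- setdiff(need, names(dat))
  if (length(miss))
    stop("pathogenic table is missing required column(s): ",
         paste(miss, collapse = ", "))
  dat$key <- variant_key(dat$chrom, dat$pos, dat$ref, dat$alt)
  if (anyDuplicated(dat$key))
    stop("pathogenic table contains duplicate keys (de-duplicate on ",
         "chrom,pos,ref,alt first): ", dat$key[duplicated(dat$key)][1])
  dat$conflicted <- as.logical(as.numeric(dat$conflicted) != 0)
  dat[, c("key", need)]
}
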