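# Fixture builders shared across test files. Everything is generated in
# code; no binary fixtures.

# A small well-formed variant-count TSV with two populations.
write_counts_tsv <- function(path, rows = NULL) {
  if (is.null(rows)) {
    rows <- data.frame(
      chrom = c("1", "2", "16"), pos = c(100L, 200L, 3293310L),
      ref = c("A", "C", "A"), alt = c("G", "T", "G"),
      annotation = c("SYN", "PRA", "PTV"),
      AC_AJ = c(10L, 25L, 40L), AN_AJ = c(4356L, 4356L, 4356L),
      AC_NFE = c(30L, 12L, 5L), AN_NFE = c(63804L, 63804L, 63804L),
      coverage_ok_NFE = c(1L, 1L, 1L),
      stringsAsFactors = FALSE)
  }
  con <- file(path, "wt")
  writeLines(paste0("#", paste(names(rows), collapse = "\t")), con)
  utils::write.table(rows, con, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  close(con)
  rows
}

# The same five variants as TSV and as a minimal VCF with AC/AN INFO keys.
write_paired_counts_fixture <- function(dir) {
  rows <- data.frame(
    chrom = c("1", "1", "2", "7", "15"),
    pos = c(100L, 250L, 900L, 5000L, 72638920L),
    ref = c("A", "C", "G", "T", "G"),
    alt = c("G", "T", "A", "C", "GGATA"),
    annotation = c("SYN", "PRA", "PTV", "OTHER", "PTV"),
    AC_AJ = c(10L, 0L, 7L, 100L, 53L),
    AN_AJ = rep(4356L, 5),
    AC_NFE = c(30L, 2L, 1L, 800L, 41L),
    AN_NFE = rep(63804L, 5),
    stringsAsFactors = FALSE)
  tsv <- file.path(dir, "counts.tsv")
  write_counts_tsv(tsv, rows)
  vcf <- file.path(dir, "counts.vcf")
  hdr <- c("##fileformat=VCFv4.2",
           "##INFO=<ID=AC_AJ,Number=1,Type=Integer,Description=\"AJ ALT count\">",
           "##INFO=<ID=AN_AJ,Number=1,Type=Integer,Description=\"AJ allele number\">",
           "##INFO=<ID=AC_NFE,Number=1,Type=Integer,Description=\"NFE ALT count\">",
           "##INFO=<ID=AN_NFE,Number=1,Type=Integer,Description=\"NFE allele number\">",
           "##INFO=<ID=ANN,Number=1,Type=String,Description=\"Annotation class\">",
           paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                 "INFO", sep = "\t"))
  body <- vapply(seq_len(nrow(rows)), function(i) {
    paste(rows$chrom[i], rows$pos[i], ".", rows$ref[i], rows$alt[i],
          ".", "PASS",
          sprintf("AC_AJ=%d;AN_AJ=%d;AC_NFE=%d;AN_NFE=%d;ANN=%s",
                  rows$AC_AJ[i], rows$AN_AJ[i], rows$AC_NFE[i],
                  rows$AN_NFE[i], rows$annotation[i]),
          sep = "\t")
  }, "")
  writeLines(c(hdr, body), vcf)
  list(tsv = tsv, vcf = vcf, rows = rows)
}

# Brute-force one-sided Fisher p by enumeration over the ALT margin,
# using plain choose() arithmetic (independent of phyper).
fisher_enum <- function(a, b, c, d) {
  m <- a + b; n <- c + d; k <- a + c
  xs <- max(0, k - n):min(k, m)
  probs <- choose(m, xs) * choose(n, k - xs) / choose(m + n, k)
  sum(probs[xs >= a])
}

# Brute-force maximizer of the Firth penalized log-likelihood on a grid,
# refined by optim; independent of the Newton path in firth_glm.
firth_grid_oracle <- function(X, y, lower = -10, upper = 10) {
  pen <- function(beta) {
    eta <- drop(X %*% beta)
    p <- plogis(eta)
    info <- crossprod(X, X * (p * (1 - p)))
    ll <- sum(y * eta - log1p(exp(eta)))
    ll + 0.5 * determinant(info, logarithm = TRUE)$modulus
  }
  k <- ncol(X)
  start <- rep(0, k)
  opt <- optim(start, function(b) -pen(b), method = "Nelder-Mead",
               control = list(maxit = 5000, reltol = 1e-14))
  opt2 <- optim(opt$par, function(b) -pen(b), method = "BFGS",
                control = list(maxit = 1000, reltol = 1e-14))
  opt2$par
}

# Genotype matrix built directly in code.
toy_genotypes <- function() {
  g <- rbind(S1 = c(0, 1, 0), S2 = c(1, 1, 0),
             S3 = c(2, 0, 1), S4 = c(0, 0, 0))
  colnames(g) <- c("1:100:A:G", "1:200:C:T", "2:300:G:A")
  genotype_matrix(g, phenotype = c(1, 1, 0, 0),
                  covariates = cbind(PC1 = c(0.1, -0.2, 0.3, 0)))
}
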