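#' Canonical variant keys
#'
#' A variant key identifies a biallelic variant as
#' `"chrom:pos:ref:alt"` with a 1-based point position (GRCh37-style
#' labels, e.g. `"16:3293310:A:G"`). Indels are kept exactly as written;
#' no normalization is performed (left-alignment/trimming is assumed done
#' upstream).
#'
#' @param chrom Chromosome label (character or integer-like).
#' @param pos 1-based position, `>= 1`.
#' @param ref,alt Reference and alternate allele strings; non-empty and
#'   distinct.
#' @return `variant_key()` returns a character vector of canonical keys.
#' @examples
#' variant_key("16", 3293310, "A", "G")
#' parse_variant_key("15:72638920:G:GGATA")
#' @export
variant_key <- function(chrom, pos, ref, alt) {
  chrom <- as.character(chrom)
  pos <- as.integer(pos)
  ref <- as.character(ref)
  alt <- as.character(alt)
  n <- max(length(chrom), length(pos), length(ref), length(alt))
  chrom <- rep_len(chrom, n); pos <- rep_len(pos, n)
  ref <- rep_len(ref, n); alt <- rep_len(alt, n)
  if (any(is.na(pos)) || any(pos < 1L))
    stop("variant position must be a 1-based integer >= 1")
  if (any(!nzchar(ref)) || any(!nzchar(alt)))
    stop("ref and alt alleles must be non-empty")
  bad <- ref == alt
  if (any(bad))
    stop("ref and alt alleles must differ (first offender: ",
         paste(chrom[bad][1], pos[bad][1], ref[bad][1], alt[bad][1], sep = ":"), ")")
  paste(chrom, pos, ref, alt, sep = ":")
}

#' @rdname variant_key
#' @param key Character vector of canonical `"chrom:pos:ref:alt"` keys.
#' @return `parse_variant_key()` returns a data.frame with columns
#'   `chrom`, `pos`, `ref`, `alt`.
#' @export
parse_variant_key <- function(key) {
  parts <- strsplit(as.character(key), ":", fixed = TRUE)
  nf <- lengths(parts)
  if (any(nf != 4L))
    stop("malformed variant key (expected chrom:pos:ref:alt): ",
         key[nf != 4L][1])
  m <- matrix(unlist(parts), ncol = 4L, byrow = TRUE)
  out <- data.frame(chrom = m[, 1], pos = as.integer(m[, 2]),
                    ref = m[, 3], alt = m[, 4],
                    stringsAsFactors = FALSE)
  # round-trip through the constructor re-checks the invariants
  variant_key(out$chrom, out$pos, out$ref, out$alt)
  out
}
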