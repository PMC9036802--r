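## Internal helpers shared across modules.

## Reverse complement of plain character strings (keeps N).
.revcomp <- function(x) {
  as.character(reverseComplement(DNAStringSet(x)))
}

## All substrings of length k of a single string, 1-based start order.
.kmers <- function(seq, k) {
  n <- nchar(seq)
  if (n < k) return(character(0))
  substring(seq, seq_len(n - k + 1L), k:n)
}

## Canonical form of a k-mer: lexicographic min of itself and its
## reverse complement, so one table covers both strands.
.canonical <- function(kmers) {
  rc <- .revcomp(kmers)
  ifelse(kmers <= rc, kmers, rc)
}

## Parse VCF GT strings ("0/0", "0|1", "./.", ".") into integer codes.
## Codes: 0 hom-ref, 1 het, 2 hom-alt (both alleles the same non-zero
## allele index), NA missing. Genotypes touching allele index > 1 at a
## biallelic site cannot occur; at multi-allelic sites any pair of equal
## non-zero indices counts as hom-alt (the site is dropped later anyway).
.parse_gt <- function(gt) {
  gt <- sub(":.*", "", gt)
  a <- strsplit(gt, "[/|]", perl = TRUE)
  vapply(a, function(p) {
    if (length(p) != 2L || any(p == ".")) return(NA_integer_)
    p <- suppressWarnings(as.integer(p))
    if (anyNA(p)) return(NA_integer_)
    if (p[1] != p[2]) return(1L)
    if (p[1] == 0L) return(0L) else return(2L)
  }, integer(1))
}

## Format a genotype code as a diploid base string given REF/ALT.
.gt_bases <- function(code, ref, alt) {
  out <- rep(NA_character_, length(code))
  out[!is.na(code) & code == 0L] <- strrep(ref, 2L)[!is.na(code) & code == 0L]
  out[!is.na(code) & code == 2L] <- strrep(alt, 2L)[!is.na(code) & code == 2L]
  het <- !is.na(code) & code == 1L
  out[het] <- paste0(ref[het], alt[het])
  out
}

## stopifnot-with-message
.check <- function(cond, ...) if (!isTRUE(cond)) stop(sprintf(...), call. = FALSE)
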