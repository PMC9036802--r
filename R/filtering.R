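#' Filter a population genotype matrix on depth, quality and zygosity
#'
#' Applies the site- and genotype-level quality rules used before
#' accession-specific SNP calling. A genotype survives only if its read
#' depth is strictly greater than `minDepth` and its genotype quality
#' strictly greater than `minGQ` (the defaults encode the literal
#' "read depth > 3, genotype quality > 30" rule, so DP 3 or GQ 30 fail);
#' genotypes failing either threshold become missing, as do heterozygous
#' calls when `homozygousOnly` (hets are blanked rather than the site
#' dropped so high-heterozygosity control panels can still be genotyped
#' downstream). Sites with more than one ALT allele are removed when
#' `dropMultiallelic`. Missing DP or GQ annotations fail the corresponding
#' threshold (conservative). Site order is preserved; filtering is
#' idempotent.
#'
#' @param x a [GenotypeData-class].
#' @param minDepth,minGQ exclusive lower bounds (defaults 3 and 30).
#' @param homozygousOnly set heterozygous calls to missing (default TRUE).
#' @param dropMultiallelic remove sites with >1 ALT allele (default TRUE).
#' @return A filtered [GenotypeData-class] with `isFiltered(x)` TRUE;
#'   `metadata(x)$filterConfig` records the thresholds.
#' @examples
#' gd <- table3Fixture()
#' filtered <- filterGenotypes(gd)
#' isFiltered(filtered)
#' @export
filterGenotypes <- function(x, minDepth = 3L, minGQ = 30L,
                            homozygousOnly = TRUE,
                            dropMultiallelic = TRUE) {
  stopifnot(is(x, "GenotypeData"))
  .check(minDepth >= 0 && minGQ >= 0, "thresholds must be non-negative")
  gt <- genotypeCalls(x)
  dp <- readDepth(x)
  gq <- genotypeQuality(x)
  fail <- is.na(dp) | dp <= minDepth | is.na(gq) | gq <= minGQ
  if (homozygousOnly)
    fail <- fail | (!is.na(gt) & gt == .GT_HET)
  gt[fail] <- NA_integer_
  dp[is.na(gt)] <- NA_integer_
  gq[is.na(gt)] <- NA_integer_
  keep <- if (dropMultiallelic) !isMultiallelic(x) else
    rep(TRUE, nrow(x))
  sites <- rowRanges(x)[keep]
  out <- GenotypeData(sites, gt[keep, , drop = FALSE],
                      DP = dp[keep, , drop = FALSE],
                      GQ = gq[keep, , drop = FALSE],
                      accessions = accessions(x),
                      indels = metadata(x)$indels,
                      filtered = TRUE)
  metadata(out)$filterConfig <- list(minDepth = minDepth, minGQ = minGQ,
                                     homozygousOnly = homozygousOnly,
                                     dropMultiallelic = dropMultiallelic)
  out
}

#' Per-site genotype tallies
#'
#' Counts hom-ref, het, hom-alt and missing genotypes at every site; the
#' four tallies always sum to the number of accessions.
#'
#' @param x a [GenotypeData-class].
#' @return A `DataFrame` with columns `chrom`, `pos`, `ref`, `alt`,
#'   `hom_ref`, `het`, `hom_alt`, `missing`.
#' @export
siteSummary <- function(x) {
  stopifnot(is(x, "GenotypeData"))
  gt <- genotypeCalls(x)
  tally <- function(code) as.integer(rowSums(!is.na(gt) & gt == code))
  DataFrame(chrom = as.character(seqnames(rowRanges(x))),
            pos = start(rowRanges(x)),
            ref = refAllele(x), alt = altAllele(x),
            hom_ref = tally(.GT_HOMREF),
            het = tally(.GT_HET),
            hom_alt = tally(.GT_HOMALT),
            missing = as.integer(rowSums(is.na(gt))))
}
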