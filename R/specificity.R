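#' Identify accession-specific SNPs
#'
#' An accession-specific SNP is a biallelic site at which exactly one
#' accession is homozygous for the alternative allele and every other
#' accession is homozygous reference. The matrix must already be filtered
#' ([filterGenotypes()]): heterozygous calls present in the input are an
#' error, and multi-allelic sites are ignored.
#'
#' Missing genotypes in the non-target accessions are governed by
#' `maxMissingOthers`: the default 0 demands an explicit hom-ref call from
#' every other accession (a missing call could hide a shared alternative
#' allele); raising it tolerates up to that proportion of missing calls
#' among the others. The target accession itself must be a called hom-alt
#' whatever the policy.
#'
#' @param x a filtered [GenotypeData-class].
#' @param maxMissingOthers maximum tolerated proportion (in [0,1]) of
#'   missing genotypes among non-target accessions (default 0).
#' @return A `GRanges`, sorted by accession then chromosome then position,
#'   with metadata columns `accession`, `REF`, `ALT`, `DP`, `GQ` (the
#'   target accession's depth and genotype quality, carried for ranking).
#' @examples
#' asnp <- callAccessionSpecific(filterGenotypes(table3Fixture()))
#' table(asnp$accession)
#' @export
callAccessionSpecific <- function(x, maxMissingOthers = 0) {
  stopifnot(is(x, "GenotypeData"))
  .check(maxMissingOthers >= 0 && maxMissingOthers <= 1,
         "maxMissingOthers must be in [0,1]")
  .check(isFiltered(x),
         "matrix is unfiltered; run filterGenotypes() first")
  gt <- genotypeCalls(x)
  .check(!any(!is.na(gt) & gt == .GT_HET),
         "matrix contains heterozygous calls; run filterGenotypes() first")
  n_acc <- ncol(gt)
  ok_site <- !isMultiallelic(x)
  n_alt <- rowSums(!is.na(gt) & gt == .GT_HOMALT)
  n_miss <- rowSums(is.na(gt))
  ## exactly one hom-alt; the target is called, so all missing calls are
  ## among the n_acc - 1 others
  hits <- which(ok_site & n_alt == 1L &
                  n_miss <= maxMissingOthers * (n_acc - 1L))
  if (length(hits) == 0L) {
    out <- GRanges()
    mcols(out) <- DataFrame(accession = character(), REF = character(),
                            ALT = character(), DP = integer(),
                            GQ = integer())
    return(out)
  }
  target_idx <- apply(gt[hits, , drop = FALSE], 1L,
                      function(r) which(!is.na(r) & r == .GT_HOMALT))
  out <- granges(rowRanges(x)[hits])
  mcols(out) <- DataFrame(
    accession = accessions(x)[target_idx],
    REF = refAllele(x)[hits],
    ALT = altAllele(x)[hits],
    DP = readDepth(x)[cbind(hits, target_idx)],
    GQ = genotypeQuality(x)[cbind(hits, target_idx)])
  ord <- order(mcols(out)$accession, as.character(seqnames(out)),
               start(out))
  out[ord]
}

#' Export accession-specific SNPs as TSV
#'
#' @param snps result of [callAccessionSpecific()] (or
#'   [annotateEffects()], whose extra columns are kept).
#' @param path output TSV path.
#' @export
writeAccessionSpecific <- function(snps, path) {
  df <- data.frame(accession = snps$accession,
                   chrom = as.character(seqnames(snps)),
                   pos = start(snps), ref = snps$REF, alt = snps$ALT,
                   dp = snps$DP, gq = snps$GQ)
  extra <- setdiff(names(mcols(snps)),
                   c("accession", "REF", "ALT", "DP", "GQ"))
  for (cn in extra) df[[cn]] <- mcols(snps)[[cn]]
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
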