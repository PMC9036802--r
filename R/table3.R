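## Published worked example: accession-specific SNPs of eight
## representative Brassica rapa accessions (two per accession), with the
## eight accessions' diploid genotypes at each of the 16 sites.
## Genotype strings are in fixture accession order.
.TABLE3_ACCESSIONS <- c("CNU_11479", "CNU_11480", "26021", "26022",
                        "28059", "28061", "CNU_11411", "CNU_11412")

.TABLE3_SITES <- list(
  ## accession, chrom, pos, ref, alt, genotypes (8 x 2 bases)
  list("CNU_11479", "A03", 21060850L, "A", "C",
       c("CC", "AA", "AA", "AA", "AA", "AA", "AA", "AA")),
  list("CNU_11479", "A06", 3079806L, "A", "G",
       c("GG", "AA", "AA", "AA", "AA", "AA", "AA", "AA")),
  list("CNU_11480", "A02", 15635917L, "C", "T",
       c("CC", "TT", "CC", "CC", "CC", "CC", "CC", "CC")),
  list("CNU_11480", "A03", 10121108L, "G", "A",
       c("GG", "AA", "GG", "GG", "GG", "GG", "GG", "GG")),
  list("26021", "A02", 18369509L, "C", "T",
       c("CC", "CC", "TT", "CC", "CC", "CC", "CC", "CC")),
  list("26021", "A06", 6118599L, "G", "A",
       c("GG", "GG", "AA", "GG", "GG", "GG", "GG", "GG")),
  list("26022", "A01", 6548614L, "A", "T",
       c("AA", "AA", "AA", "TT", "AA", "AA", "AA", "AA")),
  list("26022", "A03", 3737651L, "A", "C",
       c("AA", "AA", "AA", "CC", "AA", "AA", "AA", "AA")),
  list("28059", "A07", 21078330L, "G", "T",
       c("GG", "GG", "GG", "GG", "TT", "GG", "GG", "GG")),
  list("28059", "A07", 23181319L, "G", "T",
       c("GG", "GG", "GG", "GG", "TT", "GG", "GG", "GG")),
  list("28061", "A03", 22285257L, "G", "A",
       c("GG", "GG", "GG", "GG", "GG", "AA", "GG", "GG")),
  list("28061", "A10", 450622L, "A", "C",
       c("AA", "AA", "AA", "AA", "AA", "CC", "AA", "AA")),
  list("CNU_11411", "A07", 20012970L, "G", "A",
       c("GG", "GG", "GG", "GG", "GG", "GG", "AA", "GG")),
  list("CNU_11411", "A09", 37233481L, "C", "T",
       c("CC", "CC", "CC", "CC", "CC", "CC", "TT", "CC")),
  list("CNU_11412", "A07", 21781162L, "C", "G",
       c("CC", "CC", "CC", "CC", "CC", "CC", "CC", "GG")),
  list("CNU_11412", "A09", 42427036L, "C", "G",
       c("CC", "CC", "CC", "CC", "CC", "CC", "CC", "GG")))

#' The eight-accession worked-example genotype matrix
#'
#' A 16-site x 8-accession [GenotypeData-class] transcribing the
#' published validation set of accession-specific SNPs: two SNPs for each
#' of eight representative accessions, every site homozygous-alternative
#' in its target accession and homozygous-reference elsewhere. Depth and
#' genotype quality are not published for these sites, so the fixture
#' carries synthetic values (DP 12, GQ 60) that clear the quality
#' filters; run [filterGenotypes()] then [callAccessionSpecific()] to
#' recover the attribution.
#'
#' @return A [GenotypeData-class] of 16 sites x 8 accessions.
#' @examples
#' snps <- callAccessionSpecific(filterGenotypes(table3Fixture()))
#' table(snps$accession)
#' @export
table3Fixture <- function() {
  accs <- .TABLE3_ACCESSIONS
  n <- length(.TABLE3_SITES)
  gt <- matrix(NA_integer_, n, length(accs),
               dimnames = list(NULL, accs))
  for (i in seq_len(n)) {
    s <- .TABLE3_SITES[[i]]
    ref2 <- strrep(s[[4]], 2L); alt2 <- strrep(s[[5]], 2L)
    g <- s[[6]]
    code <- ifelse(g == ref2, 0L, ifelse(g == alt2, 2L, 1L))
    gt[i, ] <- code
  }
  sites <- GRanges(
    vapply(.TABLE3_SITES, `[[`, character(1), 2L),
    IRanges(vapply(.TABLE3_SITES, `[[`, integer(1), 3L), width = 1L))
  mcols(sites)$REF <- vapply(.TABLE3_SITES, `[[`, character(1), 4L)
  mcols(sites)$ALT <- vapply(.TABLE3_SITES, `[[`, character(1), 5L)
  dp <- matrix(12L, n, length(accs))
  gq <- matrix(60L, n, length(accs))
  GenotypeData(sites, gt, DP = dp, GQ = gq, accessions = accs)
}
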