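#' Run the full marker-development pipeline
#'
#' Convenience orchestrator chaining the pipeline stages:
#' [filterGenotypes()] (unless the matrix is already filtered),
#' [callAccessionSpecific()], optional [annotateEffects()],
#' [designCandidates()], [rankCandidates()] and [selectPanel()].
#'
#' @param x a [GenotypeData-class] (raw or filtered).
#' @param genome reference [Biostrings::DNAStringSet].
#' @param genes optional [GeneModelSet-class]; enables effect annotation
#'   and exon-priority ranking.
#' @param repeats optional repeat `GRanges`.
#' @param minDepth,minGQ genotype filter bounds (exclusive; defaults 3
#'   and 30).
#' @param maxMissingOthers missing-genotype tolerance for specificity
#'   (default 0).
#' @param maskThreshold consensus masking threshold (default 0.10).
#' @param minDuplicateMatch redundancy match length (default 100).
#' @param shortlist candidates ranked per accession (default 5).
#' @param cap markers selected per accession (default 2).
#' @param minSeparation minimum inter-marker distance in bp (default
#'   500).
#' @return A list with every intermediate: `filtered`, `snps` (annotated
#'   when `genes` given), `candidates`, `dropLog`, `ranked`, `panel`.
#' @export
runKaspPipeline <- function(x, genome, genes = NULL, repeats = NULL,
                            minDepth = 3L, minGQ = 30L,
                            maxMissingOthers = 0,
                            maskThreshold = 0.10,
                            minDuplicateMatch = 100L,
                            shortlist = 5L, cap = 2L,
                            minSeparation = 500L) {
  stopifnot(is(x, "GenotypeData"))
  filtered <- if (isFiltered(x)) x else
    filterGenotypes(x, minDepth = minDepth, minGQ = minGQ)
  snps <- callAccessionSpecific(filtered,
                                maxMissingOthers = maxMissingOthers)
  if (!is.null(genes))
    snps <- annotateEffects(snps, genes, genome)
  design <- designCandidates(snps, filtered, genome, repeats = repeats,
                             maskThreshold = maskThreshold,
                             minDuplicateMatch = minDuplicateMatch)
  ranked <- if (nrow(design$candidates))
    rankCandidates(design$candidates, shortlist = shortlist) else list()
  panel <- if (length(ranked))
    selectPanel(ranked, cap = cap, minSeparation = minSeparation)
  else new("MarkerPanel", markers = DataFrame(
    marker_id = character(), accession = character(),
    chrom = character(), pos = integer()),
    cap = as.integer(cap), minSeparation = as.integer(minSeparation),
    shortfall = character())
  list(filtered = filtered, snps = snps,
       candidates = design$candidates, dropLog = design$dropLog,
       ranked = ranked, panel = panel)
}

#' Derive a truth-based KASP call matrix for a panel
#'
#' Builds the discrete call matrix a perfect assay would produce on the
#' core collection: each marker's target accession alt-hom, every other
#' accession ref-hom. Useful for wiring evaluation tests and as the
#' starting point for perturbation experiments.
#'
#' @param panel a [MarkerPanel-class].
#' @param extraSamples optional character vector of outgroup sample ids
#'   (all ref-hom).
#' @return A [CallMatrix-class].
#' @export
truthCallMatrix <- function(panel, extraSamples = character()) {
  m <- markers(panel)
  accs <- unique(m$accession)
  samples <- c(accs, extraSamples)
  calls <- matrix("ref", nrow(m), length(samples),
                  dimnames = list(m$marker_id, samples))
  for (j in seq_len(nrow(m)))
    calls[j, m$accession[j]] <- "alt"
  groups <- setNames(c(rep("core", length(accs)),
                       rep("outgroup", length(extraSamples))), samples)
  info <- DataFrame(accession = m$accession, ref = m$ref, alt = m$alt,
                    row.names = m$marker_id)
  CallMatrix(calls, info, groups)
}
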