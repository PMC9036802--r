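## Genotype call codes used throughout: integer matrix with
##   0 = homozygous reference, 1 = heterozygous, 2 = homozygous alternative,
##   NA = missing. Constants kept internal; user-facing tables use labels.
.GT_HOMREF <- 0L
.GT_HET <- 1L
.GT_HOMALT <- 2L

.GT_LABELS <- c(`0` = "hom-ref", `1` = "het", `2` = "hom-alt")

## Discrete KASP call vocabulary for evaluation matrices.
.CALL_LEVELS <- c("ref", "het", "alt", "miss")

#' GenotypeData: a population genotype matrix
#'
#' The pipeline's central object: per-site x per-accession diploid genotype
#' calls with read depth (DP) and genotype quality (GQ), stored as a
#' \linkS4class{RangedSummarizedExperiment} with assays \code{GT}
#' (integer; 0 hom-ref, 1 het, 2 hom-alt, NA missing), \code{DP} and
#' \code{GQ}. Row ranges carry \code{REF}, \code{ALT} (comma-joined when
#' multi-allelic) and a \code{multiallelic} flag. Indel records skipped
#' while reading a VCF are kept in \code{metadata(x)$indels} as a
#' \code{GRanges} so downstream flank design can flag windows they touch.
#'
#' @slot filtered logical scalar; set by \code{\link{filterGenotypes}}.
#'
#' @seealso \code{\link{readPopulationVcf}}, \code{\link{filterGenotypes}},
#'   \code{\link{callAccessionSpecific}}
#' @exportClass GenotypeData
setClass("GenotypeData",
  contains = "RangedSummarizedExperiment",
  representation(filtered = "logical"),
  prototype(filtered = FALSE)
)

setValidity("GenotypeData", function(object) {
  msg <- NULL
  need <- c("GT", "DP", "GQ")
  if (!all(need %in% assayNames(object)))
    msg <- c(msg, sprintf("assays must include %s",
                          paste(need, collapse = ", ")))
  else {
    gt <- assay(object, "GT")
    bad <- gt[!is.na(gt)]
    if (length(bad) && !all(bad %in% c(0L, 1L, 2L)))
      msg <- c(msg, "GT values must be 0, 1, 2 or NA")
  }
  rr <- rowRanges(object)
  if (!all(c("REF", "ALT", "multiallelic") %in% names(mcols(rr))))
    msg <- c(msg, "rowRanges must carry REF, ALT and multiallelic columns")
  if (is.null(colnames(object)) || anyDuplicated(colnames(object)))
    msg <- c(msg, "accession (column) names must be present and unique")
  if (length(object@filtered) != 1L)
    msg <- c(msg, "'filtered' must be a logical scalar")
  if (is.null(msg)) TRUE else msg
})

#' Construct a GenotypeData object
#'
#' @param sites `GRanges` of width-1 SNV positions with metadata columns
#'   `REF` (single base), `ALT` (character; comma-joined if multi-allelic)
#'   and optionally `multiallelic` (derived from `ALT` when absent).
#' @param GT,DP,GQ site x accession matrices: integer genotype codes
#'   (0 hom-ref, 1 het, 2 hom-alt, NA missing), read depths and genotype
#'   qualities. `DP`/`GQ` may be NULL (all-NA matrices, which fail the
#'   quality filters -- the conservative reading of absent annotations).
#' @param accessions character vector of accession ids (column names);
#'   defaults to `colnames(GT)`.
#' @param indels optional `GRanges` of indel records excluded from the
#'   matrix (kept so flank design can drop windows they overlap).
#' @param filtered logical; TRUE only for matrices produced by
#'   [filterGenotypes()].
#' @return A [GenotypeData-class] object.
#' @export
GenotypeData <- function(sites, GT, DP = NULL, GQ = NULL,
                         accessions = colnames(GT), indels = NULL,
                         filtered = FALSE) {
  GT <- as.matrix(GT)
  storage.mode(GT) <- "integer"
  if (is.null(accessions))
    stop("accession ids are required (accessions= or colnames(GT))")
  na_mat <- function(m) {
    if (is.null(m)) {
      m <- matrix(NA_integer_, nrow(GT), ncol(GT))
    } else {
      m <- as.matrix(m)
      storage.mode(m) <- "integer"
    }
    dimnames(m) <- list(NULL, accessions)
    m
  }
  colnames(GT) <- accessions
  if (!"multiallelic" %in% names(mcols(sites)))
    mcols(sites)$multiallelic <- lengths(strsplit(mcols(sites)$ALT, ",")) > 1L
  se <- SummarizedExperiment(
    assays = list(GT = GT, DP = na_mat(DP), GQ = na_mat(GQ)),
    rowRanges = sites
  )
  obj <- new("GenotypeData", se, filtered = filtered)
  if (!is.null(indels)) metadata(obj)$indels <- indels
  obj
}

#' GeneModelSet: gene models for effect annotation
#'
#' One transcript per gene. Exons and CDS are 1-based inclusive intervals;
#' CDS intervals carry a `phase` column (bases to skip before the first
#' complete codon, as in GFF3 column 8).
#'
#' @slot genes `GRanges`, one range per gene span, with `gene_id`.
#' @slot exons `GRangesList` named by gene id.
#' @slot cds `GRangesList` named by gene id (may omit non-coding genes);
#'   each element has an integer `phase` metadata column.
#' @exportClass GeneModelSet
setClass("GeneModelSet",
  representation(genes = "GRanges", exons = "GRangesList",
                 cds = "GRangesList")
)

setValidity("GeneModelSet", function(object) {
  msg <- NULL
  ids <- mcols(object@genes)$gene_id
  if (is.null(ids) || anyDuplicated(ids))
    msg <- c(msg, "genes must carry unique gene_id")
  if (!all(names(object@exons) %in% ids))
    msg <- c(msg, "exon group names must match gene ids")
  if (!all(names(object@cds) %in% ids))
    msg <- c(msg, "cds group names must match gene ids")
  for (g in names(object@cds)) {
    cds <- object@cds[[g]]
    if (length(cds) && is.null(mcols(cds)$phase))
      msg <- c(msg, sprintf("CDS of gene %s lacks phase column", g))
  }
  if (is.null(msg)) TRUE else msg
})

#' @param genes,exons,cds see the class slots.
#' @rdname GeneModelSet-class
#' @export
GeneModelSet <- function(genes, exons, cds) {
  new("GeneModelSet", genes = genes, exons = exons, cds = cds)
}

#' MarkerPanel: the selected KASP marker set
#'
#' Holds the final, position-unique marker table (at most `cap` markers per
#' accession, windows pairwise separated by more than `minSeparation` bp)
#' plus the accessions that could not be filled to the cap.
#'
#' @slot markers `DataFrame`; one row per selected marker with columns
#'   `marker_id` (`<chrom>_<pos>`), `accession`, `chrom`, `pos`, `ref`,
#'   `alt`, `dp`, `gq`, `effect`, `region`, `rank`, `window_start`,
#'   `window_end`, `candidate_sequence`.
#' @slot cap integer; per-accession cap (default 2).
#' @slot minSeparation integer bp; windows closer than or equal to this on
#'   one chromosome are considered overlapping (default 500).
#' @slot shortfall character; accessions with fewer than `cap` markers.
#' @exportClass MarkerPanel
setClass("MarkerPanel",
  representation(markers = "DataFrame", cap = "integer",
                 minSeparation = "integer", shortfall = "character")
)

setValidity("MarkerPanel", function(object) {
  msg <- NULL
  m <- object@markers
  need <- c("marker_id", "accession", "chrom", "pos")
  if (!all(need %in% colnames(m)))
    msg <- c(msg, sprintf("markers must have columns %s",
                          paste(need, collapse = ", ")))
  else {
    if (anyDuplicated(m$marker_id))
      msg <- c(msg, "marker ids must be unique")
    if (nrow(m) && any(table(m$accession) > object@cap))
      msg <- c(msg, "per-accession cap exceeded")
    ## pairwise window separation on each chromosome
    if (nrow(m) > 1L) {
      by_chr <- split(m$pos, m$chrom)
      sep_ok <- vapply(by_chr, function(p) {
        p <- sort(p)
        length(p) < 2L || all(diff(p) > object@minSeparation)
      }, logical(1))
      if (!all(sep_ok))
        msg <- c(msg, "marker windows overlap within a chromosome")
    }
  }
  if (is.null(msg)) TRUE else msg
})

#' CallMatrix: discrete KASP genotype calls for panel evaluation
#'
#' Marker x sample grid of discrete calls. Fluorescence-to-genotype
#' clustering happens upstream on the KASP instrument; this object consumes
#' its discrete output.
#'
#' @slot calls character matrix (markers x samples) over
#'   `"ref"`, `"het"`, `"alt"`, `"miss"`.
#' @slot markerInfo `DataFrame` keyed by rowname/marker: `accession`
#'   (the marker's target), `ref`, `alt`.
#' @slot groups named character vector per sample, values from
#'   `core`, `outgroup`, `parent1`, `parent2`, `F1`, `seedlot` (or NA).
#' @exportClass CallMatrix
setClass("CallMatrix",
  representation(calls = "matrix", markerInfo = "DataFrame",
                 groups = "character")
)

setValidity("CallMatrix", function(object) {
  msg <- NULL
  cm <- object@calls
  if (!is.character(cm)) msg <- c(msg, "calls must be a character matrix")
  else if (!all(cm %in% .CALL_LEVELS))
    msg <- c(msg, sprintf("calls must be one of %s",
                          paste(.CALL_LEVELS, collapse = "/")))
  if (is.null(rownames(cm)) || is.null(colnames(cm)))
    msg <- c(msg, "calls must have marker rownames and sample colnames")
  else {
    if (!identical(rownames(cm), rownames(object@markerInfo)))
      msg <- c(msg, "markerInfo rows must match call matrix rows")
    if (length(object@groups) &&
        !identical(names(object@groups), colnames(cm)))
      msg <- c(msg, "groups must be named by sample")
  }
  if (is.null(msg)) TRUE else msg
})

#' @param calls,markerInfo,groups see the class slots.
#' @rdname CallMatrix-class
#' @export
CallMatrix <- function(calls, markerInfo, groups = character()) {
  if (length(groups) == 0L && !is.null(colnames(calls)))
    groups <- setNames(rep(NA_character_, ncol(calls)), colnames(calls))
  new("CallMatrix", calls = calls, markerInfo = markerInfo,
      groups = groups)
}

#' EvaluationReport: panel performance against a call matrix
#'
#' @slot markerResults `DataFrame`: per-marker verdicts (`specific`:
#'   alt-hom in its target accession, ref-hom in all other core samples;
#'   `outgroup_clean`: no outgroup sample alt-hom).
#' @slot accessionResults `DataFrame`: per-accession `identified` flag and
#'   number of passing markers.
#' @slot confusion `DataFrame`: unexpected (marker, sample, call) triples.
#' @slot summary list of headline numbers.
#' @exportClass EvaluationReport
setClass("EvaluationReport",
  representation(markerResults = "DataFrame",
                 accessionResults = "DataFrame",
                 confusion = "DataFrame",
                 summary = "list")
)
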