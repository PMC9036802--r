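#' @name kaspTools-accessors
#' @title Accessors for kaspTools classes
#' @description Small accessor layer so user code never touches slots or
#'   assay names directly.
#' @param x a kaspTools object.
#' @param ... passed on to methods.
NULL

#' @rdname kaspTools-accessors
#' @export
setGeneric("accessions", function(x, ...) standardGeneric("accessions"))

#' @rdname kaspTools-accessors
#' @export
setGeneric("genotypeCalls", function(x, ...) standardGeneric("genotypeCalls"))

#' @rdname kaspTools-accessors
#' @export
setGeneric("readDepth", function(x, ...) standardGeneric("readDepth"))

#' @rdname kaspTools-accessors
#' @export
setGeneric("genotypeQuality",
           function(x, ...) standardGeneric("genotypeQuality"))

#' @rdname kaspTools-accessors
#' @export
setGeneric("refAllele", function(x, ...) standardGeneric("refAllele"))

#' @rdname kaspTools-accessors
#' @export
setGeneric("altAllele", function(x, ...) standardGeneric("altAllele"))

#' @rdname kaspTools-accessors
#' @export
setGeneric("isMultiallelic",
           function(x, ...) standardGeneric("isMultiallelic"))

#' @rdname kaspTools-accessors
#' @export
setGeneric("isFiltered", function(x, ...) standardGeneric("isFiltered"))

#' @rdname kaspTools-accessors
#' @export
setGeneric("markers", function(x, ...) standardGeneric("markers"))

#' @rdname kaspTools-accessors
#' @export
setGeneric("shortfall", function(x, ...) standardGeneric("shortfall"))

#' @describeIn GenotypeData-class accession (sample) ids.
#' @param x a `GenotypeData` object.
#' @export
setMethod("accessions", "GenotypeData", function(x, ...) colnames(x))

#' @describeIn GenotypeData-class integer genotype-code matrix
#'   (0 hom-ref, 1 het, 2 hom-alt, NA missing).
#' @export
setMethod("genotypeCalls", "GenotypeData",
          function(x, ...) assay(x, "GT"))

#' @describeIn GenotypeData-class per-genotype read depth matrix.
#' @export
setMethod("readDepth", "GenotypeData", function(x, ...) assay(x, "DP"))

#' @describeIn GenotypeData-class per-genotype quality (GQ) matrix.
#' @export
setMethod("genotypeQuality", "GenotypeData",
          function(x, ...) assay(x, "GQ"))

#' @describeIn GenotypeData-class reference alleles (character).
#' @export
setMethod("refAllele", "GenotypeData",
          function(x, ...) mcols(rowRanges(x))$REF)

#' @describeIn GenotypeData-class alternative alleles (comma-joined when
#'   multi-allelic).
#' @export
setMethod("altAllele", "GenotypeData",
          function(x, ...) mcols(rowRanges(x))$ALT)

#' @describeIn GenotypeData-class logical; TRUE for sites with >1 ALT.
#' @export
setMethod("isMultiallelic", "GenotypeData",
          function(x, ...) mcols(rowRanges(x))$multiallelic)

#' @describeIn GenotypeData-class TRUE once [filterGenotypes()] has run.
#' @export
setMethod("isFiltered", "GenotypeData", function(x, ...) x@filtered)

setMethod("show", "GenotypeData", function(object) {
  cat(sprintf("GenotypeData: %d sites x %d accessions (%s)\n",
              nrow(object), ncol(object),
              if (object@filtered) "filtered" else "unfiltered"))
  n_ma <- sum(isMultiallelic(object))
  gt <- genotypeCalls(object)
  cat(sprintf("  multi-allelic sites: %d; missing genotypes: %d/%d\n",
              n_ma, sum(is.na(gt)), length(gt)))
  idl <- metadata(object)$indels
  if (!is.null(idl) && length(idl))
    cat(sprintf("  indel records carried for window flagging: %d\n",
                length(idl)))
})

#' @describeIn MarkerPanel-class the marker table (`DataFrame`).
#' @param x a `MarkerPanel`.
#' @export
setMethod("markers", "MarkerPanel", function(x, ...) x@markers)

#' @describeIn MarkerPanel-class accessions with fewer than `cap` markers.
#' @export
setMethod("shortfall", "MarkerPanel", function(x, ...) x@shortfall)

setMethod("show", "MarkerPanel", function(object) {
  m <- object@markers
  cat(sprintf("MarkerPanel: %d markers over %d accessions (cap %d)\n",
              nrow(m), length(unique(m$accession)), object@cap))
  if (length(object@shortfall))
    cat(sprintf("  short of cap: %s\n",
                paste(object@shortfall, collapse = ", ")))
})

setMethod("show", "CallMatrix", function(object) {
  cat(sprintf("CallMatrix: %d markers x %d samples\n",
              nrow(object@calls), ncol(object@calls)))
  gr <- table(object@groups, useNA = "ifany")
  cat("  groups:", paste(sprintf("%s=%d", names(gr), gr), collapse = " "),
      "\n")
})

setMethod("show", "EvaluationReport", function(object) {
  s <- object@summary
  cat("EvaluationReport\n")
  for (k in names(s))
    cat(sprintf("  %s: %s\n", k, paste(s[[k]], collapse = ", ")))
})
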