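#' Read a reference genome FASTA
#'
#' Loads all records, uppercases the sequence, and validates that
#' chromosome ids are unique and the alphabet is restricted to A/C/G/T/N
#' (assembly gaps are N runs). All pipeline coordinates are 1-based
#' inclusive positions on these sequences.
#'
#' @param path path to a FASTA file.
#' @return A [Biostrings::DNAStringSet] named by chromosome id.
#' @examples
#' fa <- tempfile(fileext = ".fa")
#' writeLines(c(">chrA", "acgtACGT", ">chrB", "GGGGCCCC"), fa)
#' genome <- readReference(fa)
#' width(genome)
#' @export
readReference <- function(path) {
  .check(file.exists(path), "FASTA file not found: %s", path)
  seqs <- tryCatch(readDNAStringSet(path),
                   error = function(e) stop(sprintf(
                     "malformed FASTA '%s': %s", path,
                     conditionMessage(e)), call. = FALSE))
  names(seqs) <- sub("\\s.*", "", names(seqs))
  dup <- unique(names(seqs)[duplicated(names(seqs))])
  .check(length(dup) == 0L, "duplicate FASTA record id(s): %s",
         paste(dup, collapse = ", "))
  seqs <- DNAStringSet(toupper(seqs))
  bad <- rowSums(letterFrequency(seqs, c("A", "C", "G", "T", "N"))) !=
    width(seqs)
  .check(!any(bad), "record(s) with bases outside A/C/G/T/N: %s",
         paste(names(seqs)[bad], collapse = ", "))
  seqs
}

#' Read a joint-called multi-sample VCF into a GenotypeData matrix
#'
#' One matrix row per SNV record, in file order; sample order is preserved
#' (or follows `sampleIds` when given). Multi-allelic SNVs are retained and
#' flagged -- [filterGenotypes()] removes them by default. Indel and
#' symbolic-allele records are skipped with a message; their positions are
#' kept in `metadata(x)$indels` so flank design can drop windows they
#' overlap. Genotypes without a usable GT (e.g. `./.`) are missing; absent
#' DP/GQ fields load as NA, which the quality filters treat as failing
#' (conservative).
#'
#' @param path path to a VCF (optionally bgzipped) with per-genotype GT
#'   and, where available, DP and GQ.
#' @param sampleIds optional character vector restricting and ordering the
#'   accessions; an unknown id is an error listing the available samples.
#' @return A [GenotypeData-class] object.
#' @export
readPopulationVcf <- function(path, sampleIds = NULL) {
  .check(file.exists(path), "VCF file not found: %s", path)
  hdr <- VariantAnnotation::scanVcfHeader(path)
  avail <- VariantAnnotation::samples(hdr)
  if (!is.null(sampleIds)) {
    missing_ids <- setdiff(sampleIds, avail)
    .check(length(missing_ids) == 0L,
           "sample(s) %s not in VCF; available: %s",
           paste(missing_ids, collapse = ", "),
           paste(avail, collapse = ", "))
    param <- ScanVcfParam(samples = sampleIds)
  } else {
    param <- ScanVcfParam()
  }
  vcf <- readVcf(path, genome = "unknown", param = param)
  rr <- SummarizedExperiment::rowRanges(vcf)
  refs <- as.character(ref(vcf))
  alt_list <- alt(vcf)
  alt_chr <- vapply(as.list(alt_list), function(a)
    paste(as.character(a), collapse = ","), character(1))
  is_snv <- nchar(refs) == 1L &
    vapply(as.list(alt_list), function(a) {
      a <- as.character(a)
      length(a) >= 1L && all(nchar(a) == 1L) && all(a %in% c("A", "C", "G", "T"))
    }, logical(1))
  n_skip <- sum(!is_snv)
  if (n_skip > 0L)
    message(sprintf("skipping %d non-SNV (indel/symbolic) record(s)", n_skip))
  indels <- granges(rr[!is_snv])
  mcols(indels) <- NULL
  gt_raw <- geno(vcf)$GT
  .check(!is.null(gt_raw), "VCF has no GT field")
  keep <- which(is_snv)
  gmat <- apply(gt_raw[keep, , drop = FALSE], 2L, .parse_gt)
  if (!is.matrix(gmat)) gmat <- matrix(gmat, nrow = length(keep),
                                       dimnames = list(NULL, colnames(gt_raw)))
  get_num <- function(field) {
    m <- geno(vcf)[[field]]
    if (is.null(m)) return(NULL)
    m <- m[keep, , drop = FALSE]
    storage.mode(m) <- "integer"
    m
  }
  sites <- granges(rr[keep])
  mcols(sites) <- NULL
  mcols(sites)$REF <- refs[keep]
  mcols(sites)$ALT <- alt_chr[keep]
  GenotypeData(sites, gmat, DP = get_num("DP"), GQ = get_num("GQ"),
               accessions = colnames(gt_raw),
               indels = if (length(indels)) indels else NULL)
}

#' Read gene models from GFF3
#'
#' Accepts the usual gene/mRNA/exon/CDS hierarchy with one transcript per
#' gene (the first is used if several are present). Exon and CDS features
#' may name either the gene or its transcript as Parent.
#'
#' @param path GFF3 file.
#' @return A [GeneModelSet-class].
#' @export
readGeneModels <- function(path) {
  .check(file.exists(path), "GFF3 file not found: %s", path)
  gr <- rtracklayer::import(path, format = "gff3")
  type <- as.character(gr$type)
  genes <- gr[type == "gene"]
  gid <- if (!is.null(genes$ID)) as.character(genes$ID) else
    as.character(genes$gene_id)
  mcols(genes) <- DataFrame(gene_id = gid)
  ## transcript -> gene map
  tx <- gr[type %in% c("mRNA", "transcript")]
  tx2gene <- setNames(
    vapply(tx$Parent, function(p) as.character(p)[1], character(1)),
    as.character(tx$ID))
  to_gene <- function(parent) {
    p <- as.character(parent)[1]
    if (p %in% names(tx2gene)) tx2gene[[p]] else p
  }
  grp <- function(feats) {
    if (length(feats) == 0L)
      return(GRangesList())
    g <- vapply(feats$Parent, to_gene, character(1))
    keepcols <- intersect("phase", names(mcols(feats)))
    mcols(feats) <- mcols(feats)[, keepcols, drop = FALSE]
    split(feats, factor(g, levels = unique(g)))
  }
  exons <- grp(gr[type == "exon"])
  cds <- grp(gr[type == "CDS"])
  ## GFF3 CDS phase arrives via rtracklayer as 'phase'; default 0 if absent
  cds <- GRangesList(lapply(cds, function(x) {
    ph <- mcols(x)$phase
    if (is.null(ph)) ph <- rep(0L, length(x))
    ph[is.na(ph)] <- 0L
    mcols(x)$phase <- as.integer(ph)
    GenomicRanges::sort(x)
  }))
  exons <- GRangesList(lapply(exons, GenomicRanges::sort))
  ## genes lacking explicit exon features: exon = gene span
  missing_ex <- setdiff(mcols(genes)$gene_id, names(exons))
  if (length(missing_ex)) {
    add <- lapply(missing_ex, function(g) {
      x <- granges(genes[mcols(genes)$gene_id == g])
      mcols(x) <- NULL
      x
    })
    exons <- c(exons, GRangesList(setNames(add, missing_ex)))
  }
  GeneModelSet(genes, exons[order(match(names(exons), mcols(genes)$gene_id))],
               cds)
}

#' Read a repeat annotation track (GFF3 or BED)
#'
#' @param path GFF3 (`.gff`/`.gff3`) or BED file of predicted repeats.
#' @return A `GRanges` with a `repeat_class` column where available.
#' @export
readRepeats <- function(path) {
  .check(file.exists(path), "repeat file not found: %s", path)
  fmt <- if (grepl("\\.bed(\\.gz)?$", path, ignore.case = TRUE)) "bed"
         else "gff3"
  gr <- rtracklayer::import(path, format = fmt)
  cls <- if (!is.null(gr$type)) as.character(gr$type)
         else if (!is.null(gr$name)) as.character(gr$name)
         else rep(NA_character_, length(gr))
  out <- granges(gr)
  mcols(out) <- DataFrame(repeat_class = cls)
  out
}

.BRACKET_RX <- "\\[[ACGT]/[ACGT]\\]"

#' Write / read KASP candidate sequences
#'
#' The submission format is a TSV with columns `marker_id`, `chrom`,
#' `pos`, `accession`, `ref`, `alt`, `candidate_sequence`; each sequence
#' contains exactly one `[REF/ALT]` token marking the diagnostic SNP
#' (sequence position 251 of the 501-bp window). The exact layout vendors
#' accept varies; this one carries everything a primer-design service
#' needs and round-trips losslessly.
#'
#' @param candidates a `DataFrame`/`data.frame` of emitted candidates, as
#'   produced by [designCandidates()].
#' @param path output TSV path.
#' @return `writeKaspCandidates` returns `path` invisibly;
#'   `readKaspCandidates` returns the candidate table as a `DataFrame`.
#' @export
writeKaspCandidates <- function(candidates, path) {
  cols <- c("marker_id", "chrom", "pos", "accession", "ref", "alt",
            "candidate_sequence")
  candidates <- as.data.frame(candidates)
  .check(all(cols %in% colnames(candidates)),
         "candidates must have columns %s", paste(cols, collapse = ", "))
  n_tok <- vapply(gregexpr(.BRACKET_RX, candidates$candidate_sequence),
                  function(m) sum(m > 0L), integer(1))
  bad <- which(n_tok != 1L)
  .check(length(bad) == 0L,
         "candidate(s) without exactly one [REF/ALT] token: %s",
         paste(candidates$marker_id[bad], collapse = ", "))
  write.table(candidates[, cols], path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}

#' @rdname writeKaspCandidates
#' @export
readKaspCandidates <- function(path) {
  .check(file.exists(path), "candidate file not found: %s", path)
  df <- read.delim(path, colClasses = c(pos = "integer"))
  DataFrame(df)
}

#' Write / read a KASP call matrix TSV
#'
#' Wide layout: columns `marker`, `accession`, `ref`, `alt`, then one
#' column per sample holding calls `ref`/`het`/`alt`/`miss`. Sample group
#' labels (core, outgroup, parent1, parent2, F1, seedlot) travel on a
#' `__group__` pseudo-row.
#'
#' @param x a [CallMatrix-class].
#' @param path TSV path.
#' @export
writeCallMatrix <- function(x, path) {
  stopifnot(is(x, "CallMatrix"))
  info <- as.data.frame(x@markerInfo)
  body <- data.frame(marker = rownames(x@calls),
                     accession = info$accession,
                     ref = info$ref, alt = info$alt,
                     as.data.frame(x@calls, optional = TRUE),
                     check.names = FALSE)
  grp <- data.frame(marker = "__group__", accession = NA, ref = NA,
                    alt = NA,
                    as.data.frame(t(unname(x@groups)), optional = TRUE),
                    check.names = FALSE)
  colnames(grp) <- colnames(body)
  write.table(rbind(grp, body), path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}

#' @rdname writeCallMatrix
#' @export
readCallMatrix <- function(path) {
  .check(file.exists(path), "call matrix file not found: %s", path)
  df <- read.delim(path, check.names = FALSE,
                   colClasses = "character")
  sample_cols <- setdiff(colnames(df), c("marker", "accession", "ref", "alt"))
  grow <- df$marker == "__group__"
  groups <- if (any(grow))
    setNames(unlist(df[which(grow)[1], sample_cols]), sample_cols)
  else setNames(rep(NA_character_, length(sample_cols)), sample_cols)
  groups[groups %in% c("NA", "")] <- NA_character_
  df <- df[!grow, , drop = FALSE]
  calls <- as.matrix(df[, sample_cols, drop = FALSE])
  rownames(calls) <- df$marker
  info <- DataFrame(accession = df$accession, ref = df$ref, alt = df$alt,
                    row.names = df$marker)
  CallMatrix(calls, info, groups)
}

#' Write a marker panel as TSV and BED
#'
#' The TSV is one row per marker; the BED (0-based half-open, as the
#' format requires) covers each marker's 501-bp window, named by marker id.
#'
#' @param panel a [MarkerPanel-class].
#' @param tsv,bed output paths (either may be NULL to skip).
#' @export
writeMarkerPanel <- function(panel, tsv = NULL, bed = NULL) {
  stopifnot(is(panel, "MarkerPanel"))
  m <- as.data.frame(markers(panel))
  if (!is.null(tsv))
    write.table(m, tsv, sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(bed)) {
    bed_df <- data.frame(chrom = m$chrom, start = m$window_start - 1L,
                         end = m$window_end, name = m$marker_id)
    write.table(bed_df, bed, sep = "\t", quote = FALSE,
                row.names = FALSE, col.names = FALSE)
  }
  invisible(panel)
}
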