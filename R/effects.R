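## Effect categories: label -> feature-type region, as reported for
## accession-specific SNP annotation. Severity order (first = most severe)
## decides the single reported label when several genes/features overlap,
## mirroring the usual impact tiers of variant annotators.
.EFFECT_SEVERITY <- c("stop-gained", "start-lost", "stop-lost",
                      "splice-acceptor", "splice-donor",
                      "non-synonymous", "stop-retained", "synonymous",
                      "intron", "upstream-5kb", "downstream-5kb",
                      "intergenic")

.EFFECT_REGION <- c(
  "non-synonymous" = "exon", "synonymous" = "exon",
  "stop-gained" = "exon", "start-lost" = "exon", "stop-lost" = "exon",
  "stop-retained" = "exon",
  "splice-acceptor" = "intron", "splice-donor" = "intron",
  "intron" = "intron",
  "upstream-5kb" = "non-coding", "downstream-5kb" = "non-coding",
  "intergenic" = "non-coding")

.GENE_FLANK <- 5000L   # upstream/downstream window (bp)
.SPLICE_BP <- 2L       # intronic bases flanking each exon junction

## Precompute per-gene lookup structures for fast per-site classification.
.prepare_genes <- function(models, genome) {
  stopifnot(is(models, "GeneModelSet"))
  ids <- mcols(models@genes)$gene_id
  lapply(seq_along(ids), function(i) {
    g <- models@genes[i]
    gid <- ids[i]
    chrom <- as.character(seqnames(g))
    strand <- as.character(strand(g))
    exons <- models@exons[[gid]]
    cds <- if (gid %in% names(models@cds)) models@cds[[gid]] else GRanges()
    info <- list(gene_id = gid, chrom = chrom, strand = strand,
                 start = start(g), end = end(g),
                 exons = cbind(start(exons), end(exons)),
                 coding_ok = FALSE)
    if (length(cds)) {
      ord <- if (strand == "-") order(start(cds), decreasing = TRUE)
             else order(start(cds))
      cds <- cds[ord]
      segs <- cbind(start(cds), end(cds))
      chr_seq <- genome[[chrom]]
      pieces <- lapply(seq_len(nrow(segs)), function(k) {
        s <- subseq(chr_seq, segs[k, 1], segs[k, 2])
        if (strand == "-") s <- reverseComplement(s)
        as.character(s)
      })
      coding <- paste(unlist(pieces), collapse = "")
      phase0 <- mcols(cds)$phase[1]
      if (is.null(phase0) || is.na(phase0)) phase0 <- 0L
      info$cds_segs <- segs
      info$cds_cum <- cumsum(c(0L, segs[, 2] - segs[, 1] + 1L))
      info$coding <- substring(coding, phase0 + 1L)
      info$phase0 <- as.integer(phase0)
      if (nchar(info$coding) %% 3L == 0L && nchar(info$coding) >= 3L) {
        info$coding_ok <- TRUE
      } else {
        warning(sprintf(
          "gene %s: CDS length %d not a codon multiple after phase; %s",
          gid, nchar(info$coding),
          "skipping coding-effect calls for this gene"), call. = FALSE)
      }
    }
    info
  })
}

## Coding-effect classification for a site inside one CDS segment.
## Returns list(label, codon_change, aa_change) or NULL if not in CDS.
.coding_effect <- function(info, pos, ref, alt) {
  segs <- info$cds_segs
  hit <- which(pos >= segs[, 1] & pos <= segs[, 2])
  if (length(hit) == 0L) return(NULL)
  if (!info$coding_ok)
    return(list(label = "intron", codon_change = NA_character_,
                aa_change = NA_character_))
  within <- if (info$strand == "-") segs[hit, 2] - pos + 1L
            else pos - segs[hit, 1] + 1L
  cpos <- info$cds_cum[hit] + within - info$phase0
  if (cpos < 1L)  # inside the phase-trimmed partial codon
    return(list(label = "intron", codon_change = NA_character_,
                aa_change = NA_character_))
  ref_t <- ref; alt_t <- alt
  if (info$strand == "-") {
    comp <- c(A = "T", C = "G", G = "C", T = "A")
    ref_t <- comp[[ref]]; alt_t <- comp[[alt]]
  }
  codon_i <- (cpos - 1L) %/% 3L
  offset <- (cpos - 1L) %% 3L + 1L
  ref_codon <- substring(info$coding, codon_i * 3L + 1L, codon_i * 3L + 3L)
  if (substring(ref_codon, offset, offset) != ref_t)
    warning(sprintf("gene %s: reference base mismatch at CDS position %d",
                    info$gene_id, cpos), call. = FALSE)
  alt_codon <- ref_codon
  substring(alt_codon, offset, offset) <- alt_t
  gc <- Biostrings::GENETIC_CODE
  ref_aa <- unname(gc[ref_codon]); alt_aa <- unname(gc[alt_codon])
  label <-
    if (codon_i == 0L && ref_codon == "ATG" && alt_codon != "ATG")
      "start-lost"
    else if (ref_aa != "*" && alt_aa == "*") "stop-gained"
    else if (ref_aa == "*" && alt_aa != "*") "stop-lost"
    else if (ref_aa == "*" && alt_aa == "*") "stop-retained"
    else if (ref_aa == alt_aa) "synonymous"
    else "non-synonymous"
  list(label = label,
       codon_change = paste0(ref_codon, ">", alt_codon),
       aa_change = paste0(ref_aa, codon_i + 1L, alt_aa))
}

## Intron / splice classification within a gene (pos known to be inside
## the gene span but outside every exon).
.intron_effect <- function(info, pos) {
  ex <- info$exons
  ex <- ex[order(ex[, 1]), , drop = FALSE]
  if (nrow(ex) < 2L) return("intron")
  for (k in seq_len(nrow(ex) - 1L)) {
    istart <- ex[k, 2] + 1L
    iend <- ex[k + 1L, 1] - 1L
    if (pos < istart || pos > iend) next
    left <- pos <= istart + .SPLICE_BP - 1L
    right <- pos >= iend - .SPLICE_BP + 1L
    if (!left && !right) return("intron")
    ## genomic-left intron edge is the donor on + strand, acceptor on -
    if (info$strand == "-") {
      if (right) return("splice-donor") else return("splice-acceptor")
    } else {
      if (left) return("splice-donor") else return("splice-acceptor")
    }
  }
  "intron"
}

## Classify one SNV against one gene; NULL when out of reach.
.gene_effect <- function(info, chrom, pos, ref, alt) {
  if (info$chrom != chrom) return(NULL)
  if (pos >= info$start && pos <= info$end) {
    if (!is.null(info$cds_segs)) {
      ce <- .coding_effect(info, pos, ref, alt)
      if (!is.null(ce)) return(c(ce, gene_id = info$gene_id))
    }
    ex <- info$exons
    in_exon <- any(pos >= ex[, 1] & pos <= ex[, 2])
    lab <- if (in_exon) "intron" else .intron_effect(info, pos)
    ## UTR-exon positions carry no category of their own here; they are
    ## reported as gene-interior non-coding ("intron")
    return(list(label = lab, codon_change = NA_character_,
                aa_change = NA_character_, gene_id = info$gene_id))
  }
  before <- pos < info$start && pos >= info$start - .GENE_FLANK
  after <- pos > info$end && pos <= info$end + .GENE_FLANK
  if (!before && !after) return(NULL)
  upstream <- (info$strand != "-" && before) ||
    (info$strand == "-" && after)
  list(label = if (upstream) "upstream-5kb" else "downstream-5kb",
       codon_change = NA_character_, aa_change = NA_character_,
       gene_id = info$gene_id)
}

#' Annotate variant effects against gene models
#'
#' Assigns each biallelic SNV exactly one effect category. Coding changes
#' are evaluated strand-aware on the spliced, phase-adjusted CDS with the
#' standard genetic code: synonymous / non-synonymous / stop-gained /
#' start-lost / stop-lost / stop-retained. The two intronic bases flanking
#' each exon junction are splice-donor (5') or splice-acceptor (3') sites.
#' Positions within 5,000 bp of a gene boundary (strand-aware, from the
#' gene span) are upstream/downstream; everything else is intergenic. When
#' several genes or features overlap, the most severe label wins under a
#' fixed order (stop-gained > start-lost > stop-lost > splice-acceptor >
#' splice-donor > non-synonymous > stop-retained > synonymous > intron >
#' upstream > downstream > intergenic). A gene whose CDS length is not a
#' codon multiple after phase adjustment triggers a warning and yields no
#' coding calls, but still anchors positional categories.
#'
#' @param sites `GRanges` of width-1 SNVs with `REF`/`ALT` metadata
#'   columns (e.g. the output of [callAccessionSpecific()]).
#' @param models a [GeneModelSet-class].
#' @param genome reference [Biostrings::DNAStringSet].
#' @return `sites` with added metadata columns `effect`, `region`
#'   (exon/intron/non-coding), `gene_id`, `codon_change` (e.g.
#'   `"AAA>AAG"`), `aa_change` (e.g. `"K12K"`).
#' @export
annotateEffects <- function(sites, models, genome) {
  stopifnot(is(sites, "GRanges"))
  prep <- .prepare_genes(models, genome)
  n <- length(sites)
  eff <- character(n); gid <- character(n)
  cod <- character(n); aac <- character(n)
  chroms <- as.character(seqnames(sites))
  poss <- start(sites)
  refs <- mcols(sites)$REF
  alts <- mcols(sites)$ALT
  .check(!is.null(refs) && !is.null(alts),
         "sites must carry REF and ALT metadata columns")
  for (i in seq_len(n)) {
    cands <- Filter(Negate(is.null),
                    lapply(prep, .gene_effect, chrom = chroms[i],
                           pos = poss[i], ref = refs[i], alt = alts[i]))
    if (length(cands) == 0L) {
      eff[i] <- "intergenic"
      gid[i] <- NA_character_; cod[i] <- NA_character_
      aac[i] <- NA_character_
    } else {
      sev <- match(vapply(cands, `[[`, character(1), "label"),
                   .EFFECT_SEVERITY)
      best <- cands[[which.min(sev)]]
      eff[i] <- best$label
      gid[i] <- best$gene_id
      cod[i] <- best$codon_change
      aac[i] <- best$aa_change
    }
  }
  mcols(sites)$effect <- eff
  mcols(sites)$region <- unname(.EFFECT_REGION[eff])
  mcols(sites)$gene_id <- gid
  mcols(sites)$codon_change <- cod
  mcols(sites)$aa_change <- aac
  sites
}

#' Effect category vocabulary
#'
#' @return A `DataFrame` of the twelve effect labels in severity order
#'   with their region class.
#' @export
effectCategories <- function() {
  DataFrame(effect = .EFFECT_SEVERITY,
            region = unname(.EFFECT_REGION[.EFFECT_SEVERITY]))
}
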