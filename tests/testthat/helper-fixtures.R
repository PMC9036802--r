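## Shared fixtures and independent oracles for the test suite.
## Everything is generated in code; no binary files.

suppressPackageStartupMessages({
  library(GenomicRanges)
  library(Biostrings)
  library(S4Vectors)
})

## Deterministic random genome as a DNAStringSet.
random_genome <- function(seed, lengths = c(chrA = 2000L)) {
  set.seed(seed)
  seqs <- vapply(lengths, function(L)
    paste(sample(c("A", "C", "G", "T"), L, replace = TRUE),
          collapse = ""), character(1))
  DNAStringSet(seqs)
}

## Small in-code GenotypeData builder. `gt` is a site x accession integer
## matrix (0/1/2/NA); ref/alt are per-site bases.
make_gd <- function(chrom, pos, ref, alt, gt, dp = NULL, gq = NULL,
                    accessions = colnames(gt), filtered = FALSE,
                    indels = NULL) {
  sites <- GRanges(chrom, IRanges(pos, width = 1L))
  mcols(sites)$REF <- ref
  mcols(sites)$ALT <- alt
  if (is.null(dp)) dp <- matrix(12L, nrow(gt), ncol(gt))
  if (is.null(gq)) gq <- matrix(60L, nrow(gt), ncol(gt))
  GenotypeData(sites, gt, DP = dp, GQ = gq, accessions = accessions,
               filtered = filtered, indels = indels)
}

## One-site GRanges for flank/effect calls.
site_gr <- function(chrom, pos, ref, alt, accession = NULL) {
  gr <- GRanges(chrom, IRanges(pos, width = 1L))
  mcols(gr)$REF <- ref
  mcols(gr)$ALT <- alt
  if (!is.null(accession)) mcols(gr)$accession <- accession
  gr
}

## ---- independent oracles -------------------------------------------

## Specificity oracle: literal per-definition scan over the call grid.
oracle_specific <- function(gt, accessions, maxMissingOthers = 0) {
  hits <- list()
  for (i in seq_len(nrow(gt))) {
    for (j in seq_len(ncol(gt))) {
      if (is.na(gt[i, j]) || gt[i, j] != 2L) next
      others <- gt[i, -j]
      n_missing <- sum(is.na(others))
      ok <- all(others == 0L, na.rm = TRUE) &&
        n_missing <= maxMissingOthers * (ncol(gt) - 1L)
      if (ok)
        hits[[length(hits) + 1L]] <- data.frame(
          site = i, accession = accessions[j],
          stringsAsFactors = FALSE)
    }
  }
  if (length(hits)) do.call(rbind, hits) else
    data.frame(site = integer(), accession = character())
}

## Redundancy oracle: naive fixed-string search. A window is redundant
## iff one of its L-mers occurs at a second locus on either strand.
oracle_redundant <- function(window_seq, window_chrom, window_start,
                             genome, L) {
  n <- nchar(window_seq)
  kmers <- substring(window_seq, seq_len(n - L + 1L), L:n)
  gseq <- as.character(genome)
  for (i in seq_along(kmers)) {
    k <- kmers[i]
    self_start <- window_start + i - 1L
    for (ch in names(gseq)) {
      hits <- gregexpr(k, gseq[[ch]], fixed = TRUE)[[1]]
      hits <- hits[hits > 0L]
      if (ch == window_chrom) hits <- setdiff(hits, self_start)
      if (length(hits)) return(TRUE)
      rc_hits <- gregexpr(as.character(
        reverseComplement(DNAString(k))), gseq[[ch]],
        fixed = TRUE)[[1]]
      if (any(rc_hits > 0L)) return(TRUE)
    }
  }
  FALSE
}

## Spliced CDS extractor used by the translate-and-diff oracle;
## written against Biostrings primitives only.
oracle_cds_seq <- function(gchar, chrom, cds_starts, cds_ends, strand) {
  o <- order(cds_starts)
  cds <- paste(substring(gchar[[chrom]], cds_starts[o], cds_ends[o]),
               collapse = "")
  if (strand == "-")
    cds <- as.character(Biostrings::reverseComplement(
      Biostrings::DNAString(cds)))
  cds
}

## Translate-and-diff oracle: classify a coding SNV by comparing the
## full translated proteins of the reference and mutated gene.
oracle_coding_effect <- function(genome, chrom, pos, alt,
                                 cds_starts, cds_ends, strand) {
  gchar <- as.list(as.character(genome))
  ref_cds <- oracle_cds_seq(gchar, chrom, cds_starts, cds_ends, strand)
  mut <- gchar
  substring(mut[[chrom]], pos, pos) <- alt
  alt_cds <- oracle_cds_seq(mut, chrom, cds_starts, cds_ends, strand)
  aa <- function(x) as.character(suppressWarnings(
    Biostrings::translate(Biostrings::DNAString(x))))
  ref_aa <- aa(ref_cds); alt_aa <- aa(alt_cds)
  first_stop <- function(p) {
    s <- regexpr("*", p, fixed = TRUE)
    if (s < 0) nchar(p) + 1L else as.integer(s)
  }
  if (!startsWith(alt_cds, "ATG") && startsWith(ref_cds, "ATG"))
    return("start-lost")
  if (identical(ref_aa, alt_aa)) {
    ## identical protein: silent; distinguish a stop>stop change
    d <- which(strsplit(ref_cds, "")[[1]] != strsplit(alt_cds, "")[[1]])
    codon <- (d - 1L) %/% 3L + 1L
    if (substring(ref_aa, codon, codon) == "*") return("stop-retained")
    return("synonymous")
  }
  if (first_stop(alt_aa) < first_stop(ref_aa)) return("stop-gained")
  if (first_stop(alt_aa) > first_stop(ref_aa)) return("stop-lost")
  "non-synonymous"
}

## Simple GeneModelSet builder around explicit exon/CDS coordinates.
make_gene <- function(gene_id, chrom, strand, exon_starts, exon_ends,
                      cds_starts = exon_starts, cds_ends = exon_ends,
                      phase = rep(0L, length(cds_starts))) {
  genes <- GRanges(chrom, IRanges(min(exon_starts), max(exon_ends)),
                   strand = strand)
  mcols(genes)$gene_id <- gene_id
  ex <- GRanges(chrom, IRanges(exon_starts, exon_ends), strand = strand)
  cd <- GRanges(chrom, IRanges(cds_starts, cds_ends), strand = strand)
  mcols(cd)$phase <- phase
  GeneModelSet(genes,
               GRangesList(setNames(list(ex), gene_id)),
               GRangesList(setNames(list(cd), gene_id)))
}

combine_genes <- function(...) {
  gs <- list(...)
  GeneModelSet(do.call(c, lapply(gs, function(g) g@genes)),
               do.call(c, lapply(gs, function(g) g@exons)),
               do.call(c, lapply(gs, function(g) g@cds)))
}

## A tiny simulated dataset shared by several test files (cached).
tiny_sim <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      sim <- simulateKaspData(seed = 42, nAccessions = 8,
                              nChromosomes = 2, chromLength = 60000,
                              specificPerAccession = 2)
      genome <- readReference(sim$fasta)
      gd <- suppressMessages(readPopulationVcf(sim$vcf))
      cache <<- list(sim = sim, genome = genome, gd = gd)
    }
    cache
  }
})
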