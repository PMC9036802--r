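#' Simulate a population resequencing dataset with planted ground truth
#'
#' Generates a reference genome, gene and repeat annotations, and a
#' joint-called population VCF that emulate the input of the marker
#' pipeline: a panel of inbred/doubled-haploid accessions whose calls are
#' homozygous reference except at planted variants. Each accession
#' receives `specificPerAccession` clean accession-specific SNPs
#' (hom-alt in that accession only, DP 12 / GQ 60, windows clear of every
#' screen and pairwise separated by more than 500 bp so a full two-marker
#' panel always exists). Confounders, each violating exactly one pipeline
#' rule, can be planted on top; the returned truth table records every
#' planted event with its expected pipeline fate.
#'
#' The genome background is i.i.d. uniform A/C/G/T, so at these scales a
#' repeated 100-mer cannot arise by chance and the redundancy screen's
#' negatives are sound. Genes are embedded as valid two-exon ORFs
#' (ATG .. sense codons .. stop) on alternating strands; planted SNPs may
#' fall inside them, exercising effect annotation and exon priority.
#'
#' @param seed integer RNG seed; identical seeds give byte-identical
#'   output files.
#' @param nAccessions number of accessions (default 50).
#' @param nChromosomes,chromLength genome shape (default 2 x 120 kb).
#' @param specificPerAccession clean specific SNPs planted per accession
#'   (default 5).
#' @param confounders named list of counts:
#'   `shared` (hom-alt in two accessions), `het` (target call
#'   heterozygous), `multiallelic` (two ALT alleles), `lowDepth` (target
#'   DP 3, the failing boundary), `lowGQ` (target GQ 30), `inRepeat`
#'   (window overlaps a repeat), `inDuplication` (window inside a
#'   duplicated segment), `nearEdge` (position 100 bp from a chromosome
#'   start), `refN` (window contains reference Ns), `indelWindow`
#'   (an indel record 50 bp from the SNP).
#' @param genesPerChrom embedded genes per chromosome (default 4).
#' @param repeatsPerChrom annotated 400-bp repeats per chromosome
#'   (default 2).
#' @param dir output directory (created if needed; default a fresh
#'   tempdir subdirectory). Files written: `genome.fa`, `population.vcf`,
#'   `genes.gff3`, `repeats.gff3`, `truth.tsv`.
#' @return A list: file paths (`fasta`, `vcf`, `genesGff`, `repeatsGff`,
#'   `truthTsv`), plus in-memory `genome` ([Biostrings::DNAStringSet]),
#'   `genes` ([GeneModelSet-class]), `repeats` (`GRanges`) and `truth`
#'   (data.frame: class, accession, chrom, pos, ref, alt,
#'   expected_fate).
#' @export
simulateKaspData <- function(seed, nAccessions = 50L, nChromosomes = 2L,
                             chromLength = 120000L,
                             specificPerAccession = 5L,
                             confounders = list(),
                             genesPerChrom = 4L, repeatsPerChrom = 2L,
                             dir = NULL) {
  set.seed(as.integer(seed))
  nAccessions <- as.integer(nAccessions)
  nChromosomes <- as.integer(nChromosomes)
  chromLength <- as.integer(chromLength)
  specificPerAccession <- as.integer(specificPerAccession)
  genesPerChrom <- as.integer(genesPerChrom)
  repeatsPerChrom <- as.integer(repeatsPerChrom)
  conf_default <- list(shared = 0L, het = 0L, multiallelic = 0L,
                       lowDepth = 0L, lowGQ = 0L, inRepeat = 0L,
                       inDuplication = 0L, nearEdge = 0L, refN = 0L,
                       indelWindow = 0L)
  unknown <- setdiff(names(confounders), names(conf_default))
  .check(length(unknown) == 0L, "unknown confounder(s): %s",
         paste(unknown, collapse = ", "))
  conf <- utils::modifyList(conf_default, confounders)
  chroms <- sprintf("chr%02d", seq_len(nChromosomes))
  accs <- sprintf("ACC%03d", seq_len(nAccessions))
  bases <- c("A", "C", "G", "T")

  ## --- genome background, one character vector per chromosome ---
  genome_chr <- lapply(chroms, function(ch)
    sample(bases, chromLength, replace = TRUE))
  names(genome_chr) <- chroms

  ## --- embed genes: two-exon ORFs, alternating strand ---
  exon1_len <- 90L; intron_len <- 150L; exon2_len <- 210L
  gene_len <- exon1_len + intron_len + exon2_len
  gene_gap <- max(gene_len + 2000L,
                  (chromLength - 4000L) %/% max(genesPerChrom, 1L))
  sense_codons <- apply(expand.grid(bases, bases, bases), 1L, paste,
                        collapse = "")
  sense_codons <- setdiff(sense_codons, c("TAA", "TAG", "TGA"))
  gene_rows <- list()
  gene_idx <- 0L
  for (ch in chroms) {
    for (g in seq_len(genesPerChrom)) {
      s <- 2000L + (g - 1L) * gene_gap
      if (s + gene_len - 1L > chromLength - 2000L) {
        stop(sprintf("infeasible config: %d genes do not fit on %s",
                     genesPerChrom, ch))
      }
      gene_idx <- gene_idx + 1L
      n_codons <- (exon1_len + exon2_len) / 3L - 2L
      coding <- paste0("ATG",
                       paste(sample(sense_codons, n_codons,
                                    replace = TRUE), collapse = ""),
                       "TAA")
      strand <- if (gene_idx %% 2L == 0L) "-" else "+"
      layout <- paste0(substring(coding, 1L, exon1_len),
                       paste(sample(bases, intron_len, replace = TRUE),
                             collapse = ""),
                       substring(coding, exon1_len + 1L,
                                 exon1_len + exon2_len))
      if (strand == "-") layout <- .revcomp(layout)
      genome_chr[[ch]][s:(s + gene_len - 1L)] <-
        strsplit(layout, "", fixed = TRUE)[[1]]
      if (strand == "+") {
        ex <- rbind(c(s, s + exon1_len - 1L),
                    c(s + exon1_len + intron_len, s + gene_len - 1L))
      } else {
        ex <- rbind(c(s, s + exon2_len - 1L),
                    c(s + exon2_len + intron_len, s + gene_len - 1L))
      }
      gene_rows[[gene_idx]] <- list(gene_id = sprintf("gene%03d",
                                                      gene_idx),
                                    chrom = ch, strand = strand,
                                    exons = ex)
    }
  }

  ## --- repeats: annotated intervals, placed between genes ---
  rep_len <- 400L
  rep_rows <- list()
  for (ch in chroms) {
    for (r in seq_len(repeatsPerChrom)) {
      s <- 2000L + (r - 1L) * gene_gap + gene_len + 700L
      .check(s + rep_len - 1L <= chromLength - 2000L,
             "infeasible config: repeats do not fit on %s", ch)
      rep_rows[[length(rep_rows) + 1L]] <-
        list(chrom = ch, start = s, end = s + rep_len - 1L)
    }
  }

  ## --- structural confounder features on chromosome 1 ---
  dup_src <- dup_dst <- NULL
  if (conf$inDuplication > 0L) {
    dup_src <- c(chromLength - 9000L, chromLength - 8001L)  # 1000 bp
    dup_dst <- c(chromLength - 4000L, chromLength - 3001L)
    genome_chr[[1L]][dup_dst[1]:dup_dst[2]] <-
      genome_chr[[1L]][dup_src[1]:dup_src[2]]
  }
  n_patch <- NULL
  if (conf$refN > 0L) {
    n_patch <- c(chromLength - 12000L, chromLength - 11951L)  # 50 bp of N
    genome_chr[[1L]][n_patch[1]:n_patch[2]] <- "N"
  }

  ## --- candidate position pool: spaced > 500 bp, clear of screens ---
  excl <- list()
  for (rr in rep_rows)
    excl[[length(excl) + 1L]] <- c(rr$chrom, rr$start, rr$end)
  if (!is.null(dup_src)) {
    excl[[length(excl) + 1L]] <- c(chroms[1L], dup_src)
    excl[[length(excl) + 1L]] <- c(chroms[1L], dup_dst)
  }
  if (!is.null(n_patch))
    excl[[length(excl) + 1L]] <- c(chroms[1L], n_patch)
  pool <- do.call(rbind, lapply(chroms, function(ch) {
    p <- seq(600L, chromLength - 600L, by = 600L)
    ok <- vapply(p, function(pos) {
      ws <- pos - 350L; we <- pos + 350L   # window plus safety margin
      for (e in excl) {
        if (e[1] != ch) next
        if (ws <= as.integer(e[3]) && we >= as.integer(e[2]))
          return(FALSE)
      }
      TRUE
    }, logical(1))
    data.frame(chrom = ch, pos = p[ok], stringsAsFactors = FALSE)
  }))
  n_pool_needed <- nAccessions * specificPerAccession +
    conf$shared + conf$het + conf$multiallelic + conf$lowDepth +
    conf$lowGQ + conf$indelWindow
  .check(nrow(pool) >= n_pool_needed,
         "infeasible config: need %d clean positions, pool has %d",
         n_pool_needed, nrow(pool))
  pool <- pool[sample.int(nrow(pool)), , drop = FALSE]
  pool_i <- 0L
  take_pool <- function() {
    pool_i <<- pool_i + 1L
    pool[pool_i, ]
  }

  ref_at <- function(ch, pos) genome_chr[[ch]][pos]
  alt_for <- function(ref, exclude = character()) {
    sample(setdiff(bases, c(ref, exclude)), 1L)
  }

  ## --- plant variants; one row per VCF site ---
  sites <- list()   # chrom,pos,ref,alt(,alt2) + genotype spec
  truth <- list()
  add_site <- function(ch, pos, ref, alt, gt, dp, gq, class, acc,
                       fate, alt2 = NA_character_) {
    sites[[length(sites) + 1L]] <<- list(
      chrom = ch, pos = pos, ref = ref, alt = alt, alt2 = alt2,
      gt = gt, dp = dp, gq = gq)
    truth[[length(truth) + 1L]] <<- data.frame(
      class = class, accession = acc, chrom = ch, pos = pos, ref = ref,
      alt = if (is.na(alt2)) alt else paste(alt, alt2, sep = ","),
      expected_fate = fate, stringsAsFactors = FALSE)
  }
  base_gt <- function() {
    list(gt = setNames(rep("0/0", nAccessions), accs),
         dp = setNames(rep(12L, nAccessions), accs),
         gq = setNames(rep(60L, nAccessions), accs))
  }
  plant <- function(class, acc, fate, ch = NULL, pos = NULL,
                    target_gt = "1/1", target_dp = 12L, target_gq = 60L,
                    second_acc = NULL, alt2 = NA_character_) {
    if (is.null(pos)) {
      slot <- take_pool(); ch <- slot$chrom; pos <- slot$pos
    }
    ref <- ref_at(ch, pos)
    alt <- alt_for(ref)
    g <- base_gt()
    g$gt[acc] <- target_gt
    g$dp[acc] <- target_dp
    g$gq[acc] <- target_gq
    if (!is.null(second_acc))
      g$gt[second_acc] <- if (!is.na(alt2)) "2/2" else "1/1"
    if (!is.na(alt2)) alt2 <- alt_for(ref, exclude = alt)
    add_site(ch, pos, ref, alt, g$gt, g$dp, g$gq, class, acc, fate,
             alt2 = alt2)
    list(chrom = ch, pos = pos)
  }

  for (acc in accs)
    for (k in seq_len(specificPerAccession))
      plant("specific", acc, "detected")
  other_of <- function(acc) accs[(match(acc, accs) %% nAccessions) + 1L]
  rotate <- function(i) accs[(i - 1L) %% nAccessions + 1L]
  ci <- 0L
  for (k in seq_len(conf$shared)) {
    ci <- ci + 1L; a <- rotate(ci)
    plant("shared", a, "dropped: shared", second_acc = other_of(a))
  }
  for (k in seq_len(conf$het)) {
    ci <- ci + 1L
    plant("het", rotate(ci), "dropped: het", target_gt = "0/1")
  }
  for (k in seq_len(conf$multiallelic)) {
    ci <- ci + 1L; a <- rotate(ci)
    plant("multiallelic", a, "dropped: multiallelic",
          second_acc = other_of(a), alt2 = "")
  }
  for (k in seq_len(conf$lowDepth)) {
    ci <- ci + 1L
    plant("lowDepth", rotate(ci), "dropped: depth", target_dp = 3L)
  }
  for (k in seq_len(conf$lowGQ)) {
    ci <- ci + 1L
    plant("lowGQ", rotate(ci), "dropped: gq", target_gq = 30L)
  }
  indel_sites <- list()
  for (k in seq_len(conf$indelWindow)) {
    ci <- ci + 1L
    at <- plant("indelWindow", rotate(ci), "dropped: indel-in-window")
    ipos <- at$pos + 50L
    iref <- paste0(ref_at(at$chrom, ipos), ref_at(at$chrom, ipos + 1L))
    indel_sites[[length(indel_sites) + 1L]] <-
      list(chrom = at$chrom, pos = ipos, ref = iref,
           alt = substring(iref, 1L, 1L))
  }
  ## structural confounders at fixed feature-bound positions (chrom 1)
  for (k in seq_len(conf$inRepeat)) {
    ci <- ci + 1L
    rr <- rep_rows[[(k - 1L) %% length(rep_rows) + 1L]]
    plant("inRepeat", rotate(ci), "dropped: repeat-overlap",
          ch = rr$chrom, pos = rr$start + 200L + (k - 1L) %/%
            length(rep_rows) * 10L)
  }
  for (k in seq_len(conf$inDuplication)) {
    ci <- ci + 1L
    plant("inDuplication", rotate(ci), "dropped: redundant",
          ch = chroms[1L], pos = dup_src[1] + 450L + (k - 1L) * 10L)
  }
  for (k in seq_len(conf$nearEdge)) {
    ci <- ci + 1L
    plant("nearEdge", rotate(ci), "dropped: edge", ch = chroms[1L],
          pos = 100L + (k - 1L) * 3L)
  }
  for (k in seq_len(conf$refN)) {
    ci <- ci + 1L
    plant("refN", rotate(ci), "dropped: ref-N", ch = chroms[1L],
          pos = n_patch[2] + 100L + (k - 1L) * 3L)
  }

  ## --- assemble outputs ---
  genome <- DNAStringSet(vapply(genome_chr, paste, character(1),
                                collapse = ""))
  names(genome) <- chroms
  ord <- order(vapply(sites, `[[`, character(1), "chrom"),
               vapply(sites, `[[`, integer(1), "pos"))
  sites <- sites[ord]
  truth_df <- do.call(rbind, truth)
  truth_df <- truth_df[order(truth_df$chrom, truth_df$pos), ]
  rownames(truth_df) <- NULL

  genes_gr <- GRanges(
    vapply(gene_rows, `[[`, character(1), "chrom"),
    IRanges(vapply(gene_rows, function(g) g$exons[1, 1], integer(1)),
            vapply(gene_rows, function(g) g$exons[2, 2], integer(1))),
    strand = vapply(gene_rows, `[[`, character(1), "strand"))
  mcols(genes_gr)$gene_id <- vapply(gene_rows, `[[`, character(1),
                                    "gene_id")
  mk_grl <- function(with_phase) {
    GRangesList(setNames(lapply(gene_rows, function(g) {
      gr <- GRanges(g$chrom, IRanges(g$exons[, 1], g$exons[, 2]),
                    strand = g$strand)
      if (with_phase) mcols(gr)$phase <- c(0L, 0L)
      gr
    }), vapply(gene_rows, `[[`, character(1), "gene_id")))
  }
  gene_models <- GeneModelSet(genes_gr, mk_grl(FALSE), mk_grl(TRUE))
  repeats_gr <- GRanges(
    vapply(rep_rows, `[[`, character(1), "chrom"),
    IRanges(vapply(rep_rows, function(r) r$start, integer(1)),
            vapply(rep_rows, function(r) r$end, integer(1))))
  mcols(repeats_gr)$repeat_class <- rep("dispersed_repeat",
                                        length(repeats_gr))

  if (is.null(dir))
    dir <- tempfile(pattern = sprintf("kaspsim_seed%d_", seed))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- list(fasta = file.path(dir, "genome.fa"),
                vcf = file.path(dir, "population.vcf"),
                genesGff = file.path(dir, "genes.gff3"),
                repeatsGff = file.path(dir, "repeats.gff3"),
                truthTsv = file.path(dir, "truth.tsv"))
  writeXStringSet(genome, paths$fasta, width = 80L)
  .write_sim_vcf(paths$vcf, chroms, chromLength, accs, sites,
                 indel_sites)
  .write_genes_gff3(paths$genesGff, gene_rows)
  .write_repeats_gff3(paths$repeatsGff, rep_rows)
  write.table(truth_df, paths$truthTsv, sep = "\t", quote = FALSE,
              row.names = FALSE)
  c(paths, list(dir = dir, genome = genome, genes = gene_models,
                repeats = repeats_gr, truth = truth_df))
}

## Minimal deterministic VCF writer for the simulator's sites.
.write_sim_vcf <- function(path, chroms, chromLength, accs, sites,
                           indel_sites) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    "##fileformat=VCFv4.2",
    sprintf("##contig=<ID=%s,length=%d>", chroms, chromLength),
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Read depth\">",
    paste0("##FORMAT=<ID=GQ,Number=1,Type=Integer,",
           "Description=\"Genotype quality\">"),
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
            "INFO", "FORMAT", accs), collapse = "\t")), con)
  recs <- c(
    lapply(sites, function(s) {
      alt <- if (!is.na(s$alt2) && nzchar(s$alt2))
        paste(s$alt, s$alt2, sep = ",") else s$alt
      list(chrom = s$chrom, pos = s$pos, ref = s$ref, alt = alt,
           gtf = paste(s$gt, s$dp, s$gq, sep = ":"))
    }),
    lapply(indel_sites, function(s) {
      list(chrom = s$chrom, pos = s$pos, ref = s$ref, alt = s$alt,
           gtf = rep("0/0:12:60", length(accs)))
    }))
  ord <- order(vapply(recs, `[[`, character(1), "chrom"),
               vapply(recs, `[[`, integer(1), "pos"))
  for (r in recs[ord])
    writeLines(paste(c(r$chrom, r$pos, ".", r$ref, r$alt, ".", "PASS",
                       ".", "GT:DP:GQ", r$gtf), collapse = "\t"), con)
  invisible(path)
}

.write_genes_gff3 <- function(path, gene_rows) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("##gff-version 3", con)
  for (g in gene_rows) {
    gs <- g$exons[1, 1]; ge <- g$exons[2, 2]
    l <- function(type, s, e, phase, attrs)
      paste(g$chrom, "sim", type, s, e, ".", g$strand, phase, attrs,
            sep = "\t")
    gid <- g$gene_id; tid <- paste0(gid, ".t1")
    writeLines(c(
      l("gene", gs, ge, ".", sprintf("ID=%s", gid)),
      l("mRNA", gs, ge, ".", sprintf("ID=%s;Parent=%s", tid, gid)),
      l("exon", g$exons[1, 1], g$exons[1, 2], ".",
        sprintf("Parent=%s", tid)),
      l("exon", g$exons[2, 1], g$exons[2, 2], ".",
        sprintf("Parent=%s", tid)),
      l("CDS", g$exons[1, 1], g$exons[1, 2], "0",
        sprintf("Parent=%s", tid)),
      l("CDS", g$exons[2, 1], g$exons[2, 2], "0",
        sprintf("Parent=%s", tid))), con)
  }
  invisible(path)
}

.write_repeats_gff3 <- function(path, rep_rows) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("##gff-version 3", con)
  for (i in seq_along(rep_rows)) {
    r <- rep_rows[[i]]
    writeLines(paste(r$chrom, "sim", "dispersed_repeat", r$start, r$end,
                     ".", "+", ".", sprintf("ID=rep%03d", i),
                     sep = "\t"), con)
  }
  invisible(path)
}
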