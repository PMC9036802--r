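## A 2000-bp genome with one plus-strand single-exon gene whose CDS is
## hand-built, so individual codon changes can be pinned exactly.
effects_fixture <- function() {
  set.seed(21)
  bg <- sample(c("A", "C", "G", "T"), 2000, replace = TRUE)
  ## CDS at 1001..1060: ATG AAA TGG CAC ... TAA (20 codons)
  coding <- paste0("ATG", "AAA", "TGG", "CAC",
                   paste(rep("GGC", 15), collapse = ""), "TAA")
  stopifnot(nchar(coding) == 60)
  bg[1001:1060] <- strsplit(coding, "")[[1]]
  genome <- DNAStringSet(c(chrA = paste(bg, collapse = "")))
  models <- make_gene("g1", "chrA", "+", 1001L, 1060L)
  list(genome = genome, models = models)
}

annotate1 <- function(fx, pos, alt) {
  ref <- as.character(subseq(fx$genome[["chrA"]], pos, pos))
  annotateEffects(site_gr("chrA", pos, ref, alt), fx$models, fx$genome)
}

test_that("hand-pinned codon changes classify correctly", {
  fx <- effects_fixture()
  ## codon 2 AAA third base: AAA>AAG both Lys -> synonymous
  syn <- annotate1(fx, 1006L, "G")
  expect_identical(syn$effect, "synonymous")
  expect_identical(syn$region, "exon")
  expect_identical(syn$codon_change, "AAA>AAG")
  expect_identical(syn$aa_change, "K2K")
  ## codon 3 TGG third base G>A: TGG>TGA -> stop gained
  stopg <- annotate1(fx, 1009L, "A")
  expect_identical(stopg$effect, "stop-gained")
  expect_identical(stopg$codon_change, "TGG>TGA")
  ## codon 1 ATG>CTG -> start lost
  startl <- annotate1(fx, 1001L, "C")
  expect_identical(startl$effect, "start-lost")
  ## terminal TAA first base T>C: TAA>CAA -> stop lost
  stopl <- annotate1(fx, 1058L, "C")
  expect_identical(stopl$effect, "stop-lost")
  ## terminal TAA third base A>G: TAA>TAG, still stop -> stop retained
  stopr <- annotate1(fx, 1060L, "G")
  expect_identical(stopr$effect, "stop-retained")
  ## codon 4 CAC first base C>G: CAC>GAC His>Asp -> non-synonymous
  mis <- annotate1(fx, 1010L, "G")
  expect_identical(mis$effect, "non-synonymous")
  expect_identical(mis$aa_change, "H4D")
})

test_that("positional categories honour the 5-kb windows", {
  fx <- effects_fixture()
  ## gene at 1001..1060 on a 2000-bp chromosome: everything upstream of
  ## it on this toy genome is < 5 kb away
  up <- annotate1(fx, 300L, "A")
  expect_identical(up$effect, "upstream-5kb")
  expect_identical(up$region, "non-coding")
  down <- annotate1(fx, 1500L, "A")
  expect_identical(down$effect, "downstream-5kb")
  ## far case needs a longer chromosome
  set.seed(22)
  long_bg <- paste(sample(c("A", "C", "G", "T"), 20000, replace = TRUE),
                   collapse = "")
  genome <- DNAStringSet(c(chrA = long_bg))
  models <- make_gene("g1", "chrA", "+", 10001L, 10060L)
  near <- annotateEffects(site_gr("chrA", 7001L,
    as.character(subseq(genome[["chrA"]], 7001L, 7001L)), "A" ),
    models, genome)
  ## 3,000 bp 5' of the gene start -> upstream
  expect_identical(near$effect, "upstream-5kb")
  far <- annotateEffects(site_gr("chrA", 4001L,
    as.character(subseq(genome[["chrA"]], 4001L, 4001L)), "A"),
    models, genome)
  ## 6,000 bp away -> intergenic
  expect_identical(far$effect, "intergenic")
  ## minus-strand gene flips the sides
  models_m <- make_gene("g1", "chrA", "-", 10001L, 10060L)
  nearm <- annotateEffects(site_gr("chrA", 7001L,
    as.character(subseq(genome[["chrA"]], 7001L, 7001L)), "A"),
    models_m, genome)
  expect_identical(nearm$effect, "downstream-5kb")
})

test_that("splice sites are the two intronic bases at each junction", {
  set.seed(23)
  bg <- sample(c("A", "C", "G", "T"), 3000, replace = TRUE)
  ## two-exon gene: exon1 1001..1090, intron 1091..1240, exon2 1241..1450
  coding <- paste0("ATG", paste(rep("GGC", 98), collapse = ""), "TAA")
  bg[1001:1090] <- strsplit(substring(coding, 1, 90), "")[[1]]
  bg[1241:1450] <- strsplit(substring(coding, 91, 300), "")[[1]]
  genome <- DNAStringSet(c(chrA = paste(bg, collapse = "")))
  models <- make_gene("g1", "chrA", "+", c(1001L, 1241L),
                      c(1090L, 1450L))
  lab <- function(pos) {
    ref <- as.character(subseq(genome[["chrA"]], pos, pos))
    alt <- setdiff(c("A", "C", "G", "T"), ref)[1]
    annotateEffects(site_gr("chrA", pos, ref, alt), models,
                    genome)$effect
  }
  expect_identical(lab(1091L), "splice-donor")     # first intron base
  expect_identical(lab(1092L), "splice-donor")
  expect_identical(lab(1093L), "intron")
  expect_identical(lab(1238L), "intron")
  expect_identical(lab(1239L), "splice-acceptor")  # last two
  expect_identical(lab(1240L), "splice-acceptor")
  ## minus strand: donor/acceptor swap genomic sides
  models_m <- make_gene("g1", "chrA", "-", c(1001L, 1241L),
                        c(1090L, 1450L))
  labm <- function(pos) {
    ref <- as.character(subseq(genome[["chrA"]], pos, pos))
    alt <- setdiff(c("A", "C", "G", "T"), ref)[1]
    annotateEffects(site_gr("chrA", pos, ref, alt), models_m,
                    genome)$effect
  }
  expect_identical(labm(1091L), "splice-acceptor")
  expect_identical(labm(1240L), "splice-donor")
})

test_that("coding labels agree with the translate-and-diff oracle", {
  sim <- tiny_sim()
  genome <- sim$genome
  models <- sim$sim$genes
  gids <- mcols(models@genes)$gene_id
  set.seed(31)
  n_draw <- 250L
  draws <- data.frame(gene = sample(gids, n_draw, replace = TRUE))
  labels <- character(n_draw); want <- character(n_draw)
  for (i in seq_len(n_draw)) {
    gid <- draws$gene[i]
    cds <- models@cds[[gid]]
    chrom <- as.character(seqnames(cds))[1]
    strand <- as.character(strand(cds))[1]
    seg <- sample(length(cds), 1L)
    pos <- sample(start(cds)[seg]:end(cds)[seg], 1L)
    ref <- as.character(subseq(genome[[chrom]], pos, pos))
    alt <- sample(setdiff(c("A", "C", "G", "T"), ref), 1L)
    got <- annotateEffects(site_gr(chrom, pos, ref, alt), models,
                           genome)
    labels[i] <- got$effect
    want[i] <- oracle_coding_effect(genome, chrom, pos, alt,
                                    start(cds), end(cds), strand)
  }
  expect_identical(labels, want)
  ## both strands exercised
  strands <- as.character(strand(models@genes))[
    match(draws$gene, gids)]
  expect_true(all(c("+", "-") %in% strands))
})

test_that("every SNV gets exactly one label and severity breaks ties", {
  fx <- effects_fixture()
  cats <- effectCategories()
  expect_identical(nrow(cats), 12L)
  set.seed(33)
  pos <- sample(100:1900, 150L)
  ref <- vapply(pos, function(p)
    as.character(subseq(fx$genome[["chrA"]], p, p)), character(1))
  alt <- vapply(ref, function(r)
    sample(setdiff(c("A", "C", "G", "T"), r), 1L), character(1))
  gr <- GRanges("chrA", IRanges(pos, width = 1L))
  mcols(gr)$REF <- ref; mcols(gr)$ALT <- alt
  ann <- annotateEffects(gr, fx$models, fx$genome)
  expect_true(all(ann$effect %in% cats$effect))
  expect_false(anyNA(ann$effect))
  ## a SNP upstream of one gene and downstream of another: upstream wins
  set.seed(34)
  bg <- paste(sample(c("A", "C", "G", "T"), 9000, replace = TRUE),
              collapse = "")
  genome2 <- DNAStringSet(c(chrA = bg))
  two <- combine_genes(
    make_gene("gL", "chrA", "+", 1001L, 1060L),
    make_gene("gR", "chrA", "+", 7001L, 7060L))
  mid <- annotateEffects(site_gr("chrA", 4000L,
    as.character(subseq(genome2[["chrA"]], 4000L, 4000L)), "A"),
    two, genome2)
  expect_identical(mid$effect, "upstream-5kb")
  expect_identical(mid$gene_id, "gR")
})

test_that("labels are invariant under whole-genome reverse complement", {
  sim <- tiny_sim()
  genome <- sim$genome
  models <- sim$sim$genes
  L <- setNames(width(genome), names(genome))
  ## mirror transform
  rc_genome <- reverseComplement(genome)
  mirror <- function(gr) {
    chrom <- as.character(seqnames(gr))
    s <- L[chrom] - end(gr) + 1L
    e <- L[chrom] - start(gr) + 1L
    st <- as.character(strand(gr))
    st[st == "+"] <- "p"; st[st == "-"] <- "+"; st[st == "p"] <- "-"
    out <- GRanges(chrom, IRanges(s, e), strand = st)
    mcols(out) <- mcols(gr)
    out
  }
  rc_models <- GeneModelSet(
    mirror(models@genes),
    GRangesList(lapply(models@exons, mirror)),
    GRangesList(lapply(models@cds, mirror)))
  set.seed(35)
  pos <- sample(300:59000, 120L)
  chrom <- sample(names(genome), 120L, replace = TRUE)
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  for (i in seq_along(pos)) {
    ref <- as.character(subseq(genome[[chrom[i]]], pos[i], pos[i]))
    alt <- sample(setdiff(c("A", "C", "G", "T"), ref), 1L)
    fwd <- annotateEffects(site_gr(chrom[i], pos[i], ref, alt),
                           models, genome)
    mpos <- L[[chrom[i]]] - pos[i] + 1L
    rev <- annotateEffects(
      site_gr(chrom[i], mpos, comp[[ref]], comp[[alt]]),
      rc_models, rc_genome)
    expect_identical(rev$effect, fwd$effect)
  }
})

test_that("broken CDS length warns and withholds coding calls", {
  set.seed(36)
  bg <- paste(sample(c("A", "C", "G", "T"), 3000, replace = TRUE),
              collapse = "")
  genome <- DNAStringSet(c(chrA = bg))
  models <- make_gene("g1", "chrA", "+", 1001L, 1060L,
                      cds_starts = 1001L, cds_ends = 1059L)  # 59 bp
  expect_warning(
    ann <- annotateEffects(site_gr("chrA", 1010L,
      as.character(subseq(genome[["chrA"]], 1010L, 1010L)), "A"),
      models, genome),
    "codon multiple")
  expect_identical(ann$region, "intron")  # positional only
})
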