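test_that("flank extraction spans pos +/- 250 and rejects edges", {
  genome <- random_genome(41, c(chrA = 1000L, tiny = 501L))
  w <- extractFlank(site_gr("chrA", 300L,
    as.character(subseq(genome[["chrA"]], 300L, 300L)), "A"), genome)
  expect_identical(c(w$start, w$end), c(50L, 550L))
  expect_identical(nchar(w$sequence), 501L)
  expect_identical(w$snp_index, 251L)
  expect_identical(substring(w$sequence, 251L, 251L), w$ref)
  expect_identical(w$sequence,
                   as.character(subseq(genome[["chrA"]], 50L, 550L)))
  ## a SNP at position 251 of a 501-bp contig: window = whole contig
  wb <- extractFlank(site_gr("tiny", 251L,
    as.character(subseq(genome[["tiny"]], 251L, 251L)), "C"), genome)
  expect_identical(c(wb$start, wb$end), c(1L, 501L))
  expect_identical(wb$sequence, as.character(genome[["tiny"]]))
  ## edges
  expect_error(extractFlank(site_gr("chrA", 100L, "A", "C"), genome),
               "edge")
  expect_error(extractFlank(site_gr("chrA", 250L, "A", "C"), genome),
               "edge")
  expect_error(extractFlank(site_gr("chrA", 751L, "A", "C"), genome),
               "edge")
  ## reference mismatch is caught
  genome2 <- genome
  ref <- as.character(subseq(genome[["chrA"]], 300L, 300L))
  wrong <- setdiff(c("A", "C", "G", "T"), ref)[1]
  expect_error(extractFlank(site_gr("chrA", 300L, wrong, "A"), genome2),
               "mismatch")
})

test_that("reference-N screen fails on any N in the window", {
  genome <- random_genome(43, c(chrA = 1200L))
  chars <- strsplit(as.character(genome[["chrA"]]), "")[[1]]
  chars[310L] <- "N"
  genome_n <- DNAStringSet(c(chrA = paste(chars, collapse = "")))
  site <- function(g, pos) site_gr("chrA", pos,
    as.character(subseq(g[["chrA"]], pos, pos)), "A")
  expect_true(screenReferenceN(extractFlank(site(genome, 400L), genome)))
  expect_false(screenReferenceN(extractFlank(site(genome_n, 400L),
                                             genome_n)))
  all_n <- DNAStringSet(c(chrA = strrep("N", 1200L)))
  w_all <- list(sequence = strrep("N", 501L))
  expect_false(screenReferenceN(w_all))
})

test_that("redundancy screen matches the naive substring oracle", {
  ## clean random 50-kb genome: every window passes
  genome <- random_genome(47, c(chrA = 30000L, chrB = 20000L))
  idx <- genomeDuplicateIndex(genome, 100L)
  expect_identical(length(idx), 0L)
  site <- function(chrom, pos) site_gr(chrom, pos,
    as.character(subseq(genome[[chrom]], pos, pos)), "A")
  w1 <- extractFlank(site("chrA", 5000L), genome)
  expect_true(screenRedundancy(w1, index = idx,
                               minDuplicateMatch = 100L))
  expect_false(oracle_redundant(w1$sequence, "chrA", w1$start, genome,
                                100L))

  ## plant an exact 200-bp copy of part of a window elsewhere
  ga <- as.character(genome[["chrA"]])
  copy <- substring(ga, 4950L, 5149L)
  gb <- as.character(genome[["chrB"]])
  substring(gb, 10000L, 10199L) <- copy
  genome_dup <- DNAStringSet(c(chrA = ga, chrB = gb))
  idx_dup <- genomeDuplicateIndex(genome_dup, 100L)
  w2 <- extractFlank(site_gr("chrA", 5000L,
    substring(ga, 5000L, 5000L), "A"), genome_dup)
  expect_false(screenRedundancy(w2, index = idx_dup,
                                minDuplicateMatch = 100L))
  expect_true(oracle_redundant(w2$sequence, "chrA", w2$start,
                               genome_dup, 100L))
  ## a window far from both copies still passes
  w3 <- extractFlank(site_gr("chrA", 20000L,
    substring(ga, 20000L, 20000L), "A"), genome_dup)
  expect_true(screenRedundancy(w3, index = idx_dup,
                               minDuplicateMatch = 100L))

  ## reverse-strand duplicate is caught
  gb_rc <- gb
  rc_copy <- as.character(reverseComplement(DNAString(copy)))
  substring(gb_rc, 15000L, 15199L) <- rc_copy
  genome_rc <- DNAStringSet(c(chrA = ga, chrB = gb_rc))
  idx_rc <- genomeDuplicateIndex(genome_rc, 100L)
  w4 <- extractFlank(site_gr("chrA", 5000L,
    substring(ga, 5000L, 5000L), "A"), genome_rc)
  expect_false(screenRedundancy(w4, index = idx_rc,
                                minDuplicateMatch = 100L))
  expect_true(oracle_redundant(w4$sequence, "chrA", w4$start,
                               genome_rc, 100L))

  ## randomized agreement sweep at a smaller threshold
  set.seed(49)
  idx80 <- genomeDuplicateIndex(genome_dup, 80L)
  for (pos in sample(300:29000, 12L)) {
    w <- extractFlank(site_gr("chrA", pos,
      substring(ga, pos, pos), "A"), genome_dup)
    got <- screenRedundancy(w, index = idx80,
                            minDuplicateMatch = 80L)
    want <- !oracle_redundant(w$sequence, "chrA", w$start, genome_dup,
                              80L)
    expect_identical(got, want)
  }
})

test_that("repeat-overlap screen agrees with brute-force intersection", {
  w <- list(chrom = "chr1", start = 1001L, end = 1501L)
  reps <- function(s, e) GRanges("chr1", IRanges(s, e))
  expect_false(screenRepeats(w, reps(1501L, 1600L)))  # 1-bp touch fails
  expect_true(screenRepeats(w, reps(1502L, 1600L)))
  expect_false(screenRepeats(w, reps(900L, 1001L)))
  expect_true(screenRepeats(w, reps(900L, 1000L)))
  expect_true(screenRepeats(w, GRanges()))
  set.seed(51)
  for (i in 1:200) {
    ws <- sample(1:5000, 1L); we <- ws + 500L
    rs <- sample(1:5500, 1L); re <- rs + sample(10:400, 1L)
    win <- list(chrom = "chr1", start = ws, end = we)
    got <- screenRepeats(win, reps(rs, re))
    want <- !(ws <= re && we >= rs)   # inclusive-interval overlap
    expect_identical(got, want)
  }
})

test_that("per-accession flank reconstruction substitutes hom-alt bases", {
  genome <- random_genome(53, c(chrA = 2000L))
  pos0 <- 1000L
  ref0 <- as.character(subseq(genome[["chrA"]], pos0, pos0))
  alt0 <- setdiff(c("A", "C", "G", "T"), ref0)[1]
  ## second site inside the window at pos 900, third outside at 200
  p2 <- 900L; p3 <- 200L
  refs <- vapply(c(pos0, p2, p3), function(p)
    as.character(subseq(genome[["chrA"]], p, p)), character(1))
  alts <- vapply(refs, function(r)
    setdiff(c("A", "C", "G", "T"), r)[1], character(1))
  gt <- matrix(c(2L, 0L, 0L,    # site pos0: A1 hom-alt
                 2L, NA, 0L,    # site 900: A1 hom-alt, A2 missing
                 0L, 2L, 0L),   # site 200: outside window
               3, 3, byrow = TRUE,
               dimnames = list(NULL, c("A1", "A2", "A3")))
  gd <- make_gd("chrA", c(pos0, p2, p3), refs, alts, gt,
                filtered = TRUE)
  w <- extractFlank(site_gr("chrA", pos0, ref0, alt0), genome)
  fl <- reconstructAccessionFlanks(w, gd)
  expect_identical(length(fl$seqs), 3L)
  ## A3 carries nothing: equals reference
  expect_identical(fl$seqs[["A3"]], w$sequence)
  ## A1 differs exactly at window offsets of pos0 and 900
  d1 <- which(strsplit(fl$seqs[["A1"]], "")[[1]] !=
                strsplit(w$sequence, "")[[1]])
  expect_identical(d1, c(p2 - w$start + 1L, 251L))
  expect_identical(substring(fl$seqs[["A1"]], 251L, 251L), alt0)
  ## A2's missing genotype leaves reference but is tallied
  expect_identical(fl$seqs[["A2"]], w$sequence)
  expect_identical(fl$nonref[p2 - w$start + 1L], 1L)
  expect_identical(sum(fl$nonref), 1L)
  expect_false(fl$indel_in_window)
  ## an indel record inside the window raises the flag
  gd_i <- make_gd("chrA", c(pos0, p2, p3), refs, alts, gt,
                  filtered = TRUE,
                  indels = GRanges("chrA", IRanges(980L, 981L)))
  expect_true(reconstructAccessionFlanks(w, gd_i)$indel_in_window)
  gd_o <- make_gd("chrA", c(pos0, p2, p3), refs, alts, gt,
                  filtered = TRUE,
                  indels = GRanges("chrA", IRanges(100L, 101L)))
  expect_false(reconstructAccessionFlanks(w, gd_o)$indel_in_window)
})

test_that("consensus masks strictly above the threshold", {
  ref <- strrep("A", 20L)
  mk <- function(n_alt, len = 20L, at = 5L) {
    ## 20 accessions; n_alt of them carry C at position `at`
    seqs <- rep(ref, 20L)
    for (i in seq_len(n_alt)) {
      s <- strsplit(seqs[i], "")[[1]]; s[at] <- "C"
      seqs[i] <- paste(s, collapse = "")
    }
    seqs
  }
  ## 3/20 = 15% > 10% -> masked
  c3 <- buildConsensus(mk(3L), ref, maskThreshold = 0.10, snpIndex = 10L)
  expect_identical(substring(c3$consensus, 5L, 5L), "N")
  expect_identical(c3$masked_count, 1L)
  ## 2/20 = 10%, not strictly greater -> unmasked
  c2 <- buildConsensus(mk(2L), ref, maskThreshold = 0.10, snpIndex = 10L)
  expect_identical(c2$consensus, ref)
  expect_identical(c2$masked_count, 0L)
  ## no variation -> identity
  c0 <- buildConsensus(rep(ref, 20L), ref, snpIndex = 10L)
  expect_identical(c0$consensus, ref)
  ## missing tally counts toward masking ("missing or alternative")
  nr <- integer(20L); nr[7L] <- 3L
  cm <- buildConsensus(rep(ref, 20L), ref, maskThreshold = 0.10,
                       snpIndex = 10L, nonref = nr)
  expect_identical(substring(cm$consensus, 7L, 7L), "N")
  ## the SNP position itself is never masked
  seqs <- mk(10L, at = 10L)
  cs <- buildConsensus(seqs, ref, maskThreshold = 0.10, snpIndex = 10L)
  expect_identical(substring(cs$consensus, 10L, 10L), "A")
  ## unequal lengths rejected
  expect_error(buildConsensus(c("AAAA", "AAA"), "AAAA"), "equal length")
})

test_that("masking is monotone in alternative-carrier count", {
  ref <- strrep("G", 30L)
  set.seed(57)
  masked_at <- function(n_alt) {
    seqs <- rep(ref, 25L)
    for (i in seq_len(n_alt)) {
      s <- strsplit(seqs[i], "")[[1]]; s[12L] <- "T"
      seqs[i] <- paste(s, collapse = "")
    }
    substring(buildConsensus(seqs, ref, snpIndex = 1L)$consensus,
              12L, 12L) == "N"
  }
  state <- vapply(0:25, masked_at, logical(1))
  ## once masked, adding carriers never unmasks
  expect_true(all(diff(as.integer(state)) >= 0L))
})

test_that("candidate assembly brackets the variant at position 251", {
  genome <- random_genome(59, c(chrA = 1200L))
  pos <- 600L
  ref <- as.character(subseq(genome[["chrA"]], pos, pos))
  alt <- setdiff(c("A", "C", "G", "T"), ref)[1]
  w <- extractFlank(site_gr("chrA", pos, ref, alt), genome)
  cand <- makeCandidate(w, w$sequence, "ACC1", maskedCount = 0L)
  expect_identical(nchar(cand$candidate_sequence), 505L)  # 501 + 4
  tok <- regmatches(cand$candidate_sequence,
                    regexpr("\\[[ACGT]/[ACGT]\\]",
                            cand$candidate_sequence))
  expect_identical(tok, sprintf("[%s/%s]", ref, alt))
  ## bracket opens where sequence position 251 sat
  expect_identical(substring(cand$candidate_sequence, 1L, 250L),
                   substring(w$sequence, 1L, 250L))
  expect_identical(substring(cand$candidate_sequence, 256L, 505L),
                   substring(w$sequence, 252L, 501L))
  expect_identical(cand$marker_id, "chrA_600")
  ## masked neighbour at 250 shows as N[REF/ALT]
  cons <- w$sequence
  substring(cons, 250L, 250L) <- "N"
  cand2 <- makeCandidate(w, cons, "ACC1")
  expect_match(cand2$candidate_sequence,
               sprintf("N\\[%s/%s\\]", ref, alt))
  ## flagged candidates are refused
  expect_error(makeCandidate(w, w$sequence, "ACC1",
                             flags = "redundant"), "flagged")
})

test_that("screen order does not change the surviving set", {
  sim <- tiny_sim()
  res <- runKaspPipeline(sim$gd, sim$genome, genes = sim$sim$genes,
                         repeats = sim$sim$repeats)
  snps <- res$snps
  filtered <- res$filtered
  idx <- genomeDuplicateIndex(sim$genome, 100L)
  verdicts <- function(order_fun) {
    vapply(seq_along(snps), function(i) {
      w <- tryCatch(extractFlank(snps[i], sim$genome),
                    error = function(e) NULL)
      if (is.null(w)) return(FALSE)
      screens <- list(
        n = function() screenReferenceN(w),
        red = function() screenRedundancy(w, index = idx,
                                          minDuplicateMatch = 100L),
        rep = function() screenRepeats(w, sim$sim$repeats))
      all(vapply(order_fun(screens), function(f) f(), logical(1)))
    }, logical(1))
  }
  a <- verdicts(identity)
  b <- verdicts(rev)
  c3 <- verdicts(function(s) s[c(2, 3, 1)])
  expect_identical(a, b)
  expect_identical(a, c3)
})
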