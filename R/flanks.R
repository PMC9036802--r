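.FLANK_BP <- 250L          # bases either side of the SNP
.WINDOW_BP <- 501L         # total window length
.SNP_INDEX <- 251L         # 1-based SNP position within the window

#' Extract the 501-bp flanking window of a SNP
#'
#' The window spans positions pos-250 .. pos+250 of the reference, so the
#' variant sits at window position 251. Sites closer than 250 bp to a
#' chromosome end cannot host a full window and are rejected.
#'
#' @param site length-1 `GRanges` with `REF` (and usually `ALT`) metadata.
#' @param genome reference [Biostrings::DNAStringSet].
#' @param flank half-window size in bp (default 250).
#' @return A `FlankWindow`: a list with fields `chrom`, `pos`, `ref`,
#'   `alt`, `start`, `end`, `sequence` (reference substring) and
#'   `snp_index` (251 for the default flank).
#' @export
extractFlank <- function(site, genome, flank = .FLANK_BP) {
  stopifnot(is(site, "GRanges"), length(site) == 1L)
  chrom <- as.character(seqnames(site))
  .check(chrom %in% names(genome), "chromosome %s not in genome", chrom)
  pos <- start(site)
  clen <- width(genome)[match(chrom, names(genome))]
  if (pos <= flank || pos > clen - flank)
    stop(sprintf("edge: site %s:%d too close to a chromosome end", chrom,
                 pos), call. = FALSE)
  seq <- as.character(subseq(genome[[chrom]], pos - flank, pos + flank))
  ref <- mcols(site)$REF
  wref <- substring(seq, flank + 1L, flank + 1L)
  .check(is.null(ref) || wref == ref,
         "reference mismatch at %s:%d (genome %s, site %s)",
         chrom, pos, wref, ref)
  structure(list(chrom = chrom, pos = pos,
                 ref = wref,
                 alt = if (!is.null(mcols(site)$ALT)) mcols(site)$ALT
                       else NA_character_,
                 start = pos - flank, end = pos + flank,
                 sequence = seq, snp_index = flank + 1L),
            class = "FlankWindow")
}

#' Screen a window for reference assembly gaps
#'
#' @param window a `FlankWindow`.
#' @return TRUE (pass) iff the reference window contains no N.
#' @export
screenReferenceN <- function(window) {
  !grepl("N", window$sequence, fixed = TRUE)
}

#' Build the genome-wide duplicate k-mer index for the redundancy screen
#'
#' Flanking-sequence redundancy (a second locus similar enough to
#' cross-amplify) is operationalized as an exact repeated substring of at
#' least `minLen` bp anywhere in the genome, on either strand. Such a
#' repeat exists iff some `minLen`-mer occurs at two loci, so the index
#' is simply the set of canonical (strand-folded) `minLen`-mers seen more
#' than once genome-wide.
#'
#' @param genome reference [Biostrings::DNAStringSet].
#' @param minLen duplicate match length in bp (default 100).
#' @return Character vector of duplicated canonical k-mers (class
#'   `DuplicateIndex`), consumed by [screenRedundancy()].
#' @export
genomeDuplicateIndex <- function(genome, minLen = 100L) {
  .check(minLen >= 1L && minLen <= .WINDOW_BP,
         "minLen must be in [1, %d]", .WINDOW_BP)
  kmers <- unlist(lapply(as.character(genome), .kmers, k = minLen),
                  use.names = FALSE)
  kmers <- kmers[!grepl("N", kmers, fixed = TRUE)]
  canon <- .canonical(kmers)
  dt <- data.table(k = canon)
  dup <- dt[, .N, by = "k"][N >= 2L, k]
  structure(dup, class = c("DuplicateIndex", "character"),
            minLen = as.integer(minLen))
}

#' Screen a window for genome-wide sequence redundancy
#'
#' Fails iff some substring of the window of length at least
#' `minDuplicateMatch` also occurs at a second genomic locus (forward or
#' reverse-complement). Exact matching is a deterministic stand-in for a
#' BLAST-style search; windows drawn from unique sequence pass.
#'
#' @param window a `FlankWindow`.
#' @param genome reference genome (used when `index` is NULL).
#' @param minDuplicateMatch duplicate length threshold in bp (default 100).
#' @param index optional prebuilt [genomeDuplicateIndex()] (recommended
#'   when screening many windows).
#' @return TRUE (pass) iff the window shares no such substring.
#' @export
screenRedundancy <- function(window, genome = NULL,
                             minDuplicateMatch = 100L, index = NULL) {
  if (is.null(index)) {
    .check(!is.null(genome), "either genome or index is required")
    index <- genomeDuplicateIndex(genome, minDuplicateMatch)
  } else {
    .check(attr(index, "minLen") == minDuplicateMatch,
           "index was built for minLen %d, not %d",
           attr(index, "minLen"), minDuplicateMatch)
  }
  wk <- .canonical(.kmers(window$sequence, minDuplicateMatch))
  !any(wk %in% index)
}

#' Screen a window for repeat overlap
#'
#' @param window a `FlankWindow`.
#' @param repeats `GRanges` of predicted repeats ([readRepeats()]).
#' @return TRUE (pass) iff the window shares no base with any repeat
#'   interval (a single shared bp counts as overlap).
#' @export
screenRepeats <- function(window, repeats) {
  if (is.null(repeats) || length(repeats) == 0L) return(TRUE)
  w <- GRanges(window$chrom, IRanges(window$start, window$end))
  !overlapsAny(w, repeats, ignore.strand = TRUE)
}

#' Reconstruct per-accession flanking sequences
#'
#' For every accession, substitutes its homozygous-alternative alleles at
#' biallelic SNVs inside the window into the reference sequence; the
#' alignment is positional by construction since only SNVs are
#' substituted. Missing (and any residual heterozygous) genotypes leave
#' the reference base but are tallied per position so the consensus step
#' can count them as non-reference, honouring the "missing or
#' alternative" masking rule without inventing sequence. Windows touched
#' by an indel record carried in `metadata(x)$indels` are flagged: an
#' accession indel would break the positional alignment, so such windows
#' are dropped rather than gap-aligned.
#'
#' @param window a `FlankWindow`.
#' @param x a filtered [GenotypeData-class] covering the window's
#'   chromosome.
#' @return An `AccessionFlanks` list: `seqs` (named character vector of
#'   501-base sequences), `nonref` (integer vector per window position:
#'   count of missing/het genotypes whose base is unknown), `n`
#'   (accession count), `indel_in_window` (flag).
#' @export
reconstructAccessionFlanks <- function(window, x) {
  stopifnot(is(x, "GenotypeData"))
  rr <- rowRanges(x)
  in_win <- which(as.character(seqnames(rr)) == window$chrom &
                    start(rr) >= window$start & start(rr) <= window$end &
                    !isMultiallelic(x))
  gt <- genotypeCalls(x)
  acc <- accessions(x)
  n <- length(acc)
  wlen <- nchar(window$sequence)
  seqs <- setNames(rep(window$sequence, n), acc)
  nonref <- integer(wlen)
  for (i in in_win) {
    off <- start(rr)[i] - window$start + 1L
    g <- gt[i, ]
    alt <- altAllele(x)[i]
    carriers <- which(!is.na(g) & g == .GT_HOMALT)
    if (length(carriers))
      substring(seqs[carriers], off, off) <- alt
    nonref[off] <- nonref[off] + sum(is.na(g) | g == .GT_HET)
  }
  indels <- metadata(x)$indels
  indel_hit <- !is.null(indels) && length(indels) > 0L &&
    overlapsAny(GRanges(window$chrom,
                        IRanges(window$start, window$end)),
                indels, ignore.strand = TRUE)
  structure(list(seqs = seqs, nonref = nonref, n = n,
                 indel_in_window = isTRUE(indel_hit)),
            class = "AccessionFlanks")
}

#' Build the masked consensus of aligned accession flanks
#'
#' For every window position except the target SNP position, the fraction
#' of accessions whose base is non-reference (alternative allele, or
#' unknown because the genotype is missing/het) is computed; positions
#' where that fraction is strictly greater than `maskThreshold` (default
#' 10\%) are masked with N so primers avoid population-polymorphic sites.
#' The target position itself always keeps the reference base -- it is
#' variable by definition and receives the allele bracket instead.
#'
#' @param flanks an `AccessionFlanks` object, or a plain character vector
#'   of equal-length aligned sequences.
#' @param reference the window's reference sequence (taken from the
#'   `AccessionFlanks` consensus of inputs when those are given with
#'   `window`).
#' @param maskThreshold masking threshold as a proportion (default 0.10);
#'   masking applies strictly above it.
#' @param snpIndex window position exempt from masking (default 251).
#' @param nonref optional integer vector of additional per-position
#'   non-reference counts (unknown bases); used automatically when
#'   `flanks` is an `AccessionFlanks`.
#' @return A list: `consensus` (character string over A/C/G/T/N) and
#'   `masked_count`.
#' @export
buildConsensus <- function(flanks, reference, maskThreshold = 0.10,
                           snpIndex = .SNP_INDEX, nonref = NULL) {
  if (inherits(flanks, "AccessionFlanks")) {
    if (is.null(nonref)) nonref <- flanks$nonref
    flanks <- flanks$seqs
  }
  .check(length(flanks) >= 1L, "at least one sequence is required")
  wlen <- unique(nchar(flanks))
  .check(length(wlen) == 1L, "sequences must have equal length")
  .check(nchar(reference) == wlen,
         "reference length does not match the sequences")
  if (is.null(nonref)) nonref <- integer(wlen)
  .check(length(nonref) == wlen, "nonref must have one entry per position")
  n <- length(flanks)
  mat <- matrix(unlist(strsplit(flanks, "", fixed = TRUE), use.names = FALSE),
                nrow = n, byrow = TRUE)
  refv <- strsplit(reference, "", fixed = TRUE)[[1]]
  ## unknown bases (N) in an input sequence count as differing
  diff_n <- colSums(mat != rep(refv, each = n)) + nonref
  frac <- diff_n / n
  mask <- frac > maskThreshold
  if (snpIndex >= 1L && snpIndex <= wlen) mask[snpIndex] <- FALSE
  cons <- refv
  cons[mask] <- "N"
  list(consensus = paste(cons, collapse = ""),
       masked_count = sum(mask))
}

#' Assemble a KASP candidate record
#'
#' Replaces window position 251 of the masked consensus with the
#' `[REF/ALT]` allele bracket. Candidates carrying any screening flag are
#' refused.
#'
#' @param window a `FlankWindow`.
#' @param consensus the masked consensus string ([buildConsensus()]).
#' @param accession target accession id.
#' @param flags character vector of failed screens (must be empty).
#' @param maskedCount number of masked positions (bookkeeping).
#' @return A one-row `data.frame` with the candidate fields, including
#'   `candidate_sequence` containing exactly one bracket token.
#' @export
makeCandidate <- function(window, consensus, accession,
                          flags = character(), maskedCount = NA_integer_) {
  .check(length(flags) == 0L,
         "refusing to emit flagged candidate (%s)",
         paste(flags, collapse = ", "))
  .check(nchar(consensus) == nchar(window$sequence),
         "consensus length does not match the window")
  i <- window$snp_index
  cand <- paste0(substring(consensus, 1L, i - 1L),
                 "[", window$ref, "/", window$alt, "]",
                 substring(consensus, i + 1L, nchar(consensus)))
  data.frame(marker_id = sprintf("%s_%d", window$chrom, window$pos),
             chrom = window$chrom, pos = window$pos,
             accession = accession, ref = window$ref, alt = window$alt,
             window_start = window$start, window_end = window$end,
             masked_count = maskedCount,
             candidate_sequence = cand,
             stringsAsFactors = FALSE)
}

#' Design KASP candidate sequences for accession-specific SNPs
#'
#' Runs the full flank-design stage for each accession-specific SNP:
#' extract the 501-bp reference window, screen it against reference Ns,
#' genome-wide redundancy and repeat overlap, drop windows touched by
#' indel records, reconstruct per-accession flanks from the genotype
#' matrix, build the masked consensus, and emit the bracketed candidate.
#' Sites failing any step land in the drop log with a reason
#' (`edge`, `ref-N`, `redundant`, `repeat-overlap`, `indel-in-window`).
#'
#' @param snps `GRanges` from [callAccessionSpecific()] (optionally with
#'   [annotateEffects()] columns, which are carried through).
#' @param x the filtered [GenotypeData-class] the SNPs came from.
#' @param genome reference [Biostrings::DNAStringSet].
#' @param repeats optional repeat `GRanges` ([readRepeats()]).
#' @param maskThreshold consensus masking threshold (default 0.10).
#' @param minDuplicateMatch redundancy match length in bp (default 100).
#' @param flank half-window in bp (default 250).
#' @return A list: `candidates` (`DataFrame`, one row per emitted
#'   candidate) and `dropLog` (`DataFrame`: accession, chrom, pos,
#'   reason).
#' @export
designCandidates <- function(snps, x, genome, repeats = NULL,
                             maskThreshold = 0.10,
                             minDuplicateMatch = 100L,
                             flank = .FLANK_BP) {
  stopifnot(is(snps, "GRanges"), is(x, "GenotypeData"))
  index <- genomeDuplicateIndex(genome, minDuplicateMatch)
  cand_rows <- list()
  drop_rows <- list()
  extra <- intersect(c("DP", "GQ", "effect", "region", "gene_id"),
                     names(mcols(snps)))
  for (i in seq_along(snps)) {
    site <- snps[i]
    acc <- mcols(site)$accession
    rec_drop <- function(reason) {
      drop_rows[[length(drop_rows) + 1L]] <<- data.frame(
        accession = acc, chrom = as.character(seqnames(site)),
        pos = start(site), reason = reason, stringsAsFactors = FALSE)
    }
    window <- tryCatch(extractFlank(site, genome, flank = flank),
                       error = function(e) {
                         if (grepl("^edge", conditionMessage(e)))
                           NULL
                         else stop(e)
                       })
    if (is.null(window)) { rec_drop("edge"); next }
    if (!screenReferenceN(window)) { rec_drop("ref-N"); next }
    if (!screenRedundancy(window, minDuplicateMatch = minDuplicateMatch,
                          index = index)) { rec_drop("redundant"); next }
    if (!screenRepeats(window, repeats)) { rec_drop("repeat-overlap"); next }
    fl <- reconstructAccessionFlanks(window, x)
    if (fl$indel_in_window) { rec_drop("indel-in-window"); next }
    cons <- buildConsensus(fl, reference = window$sequence,
                           maskThreshold = maskThreshold,
                           snpIndex = window$snp_index)
    row <- makeCandidate(window, cons$consensus, acc,
                         maskedCount = cons$masked_count)
    for (cn in extra) row[[tolower(cn)]] <- mcols(site)[[cn]]
    cand_rows[[length(cand_rows) + 1L]] <- row
  }
  empty_drop <- DataFrame(accession = character(), chrom = character(),
                          pos = integer(), reason = character())
  list(candidates = if (length(cand_rows))
         DataFrame(do.call(rbind, cand_rows)) else DataFrame(),
       dropLog = if (length(drop_rows))
         DataFrame(do.call(rbind, drop_rows)) else empty_drop)
}
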