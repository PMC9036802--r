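#' Rank screened candidates within each accession
#'
#' Ordering follows marker-development practice here: exonic candidates
#' are given priority, then higher read depth, then higher genotype
#' quality; chromosome and position (ascending) break remaining ties so
#' the order is total and deterministic. Only the top `shortlist`
#' candidates per accession (default 5) go forward to panel selection.
#'
#' @param candidates the `candidates` table from [designCandidates()]
#'   (columns `accession`, `dp`, `gq`, `chrom`, `pos`, and `region` when
#'   effects were annotated; without `region` all candidates rank as
#'   non-exonic).
#' @param shortlist candidates retained per accession (default 5).
#' @return A named list (one element per accession, names sorted) of
#'   `DataFrame`s in rank order with a `rank` column.
#' @export
rankCandidates <- function(candidates, shortlist = 5L) {
  df <- as.data.frame(candidates)
  .check(nrow(df) > 0L, "no candidates to rank")
  if (!"region" %in% colnames(df)) df$region <- NA_character_
  if (!"dp" %in% colnames(df)) df$dp <- NA_integer_
  if (!"gq" %in% colnames(df)) df$gq <- NA_integer_
  exonic <- !is.na(df$region) & df$region == "exon"
  out <- lapply(split(seq_len(nrow(df)), df$accession), function(idx) {
    o <- order(!exonic[idx],                      # exon first
               -replace(df$dp[idx], is.na(df$dp[idx]), -1L),
               -replace(df$gq[idx], is.na(df$gq[idx]), -1L),
               df$chrom[idx], df$pos[idx])
    sel <- idx[o][seq_len(min(shortlist, length(idx)))]
    res <- DataFrame(df[sel, , drop = FALSE])
    res$rank <- seq_len(nrow(res))
    rownames(res) <- NULL
    res
  })
  out[order(names(out))]
}

#' Select the final marker panel
#'
#' Greedy sweep over accessions (in list order) and ranks: a candidate is
#' taken unless its 501-bp window overlaps an already-selected marker's
#' window (same chromosome, positions `minSeparation` bp or closer) --
#' overlapping amplicons across markers cause cross-talk and false
#' positives in pooled purity assays. Selection stops at `cap` markers
#' per accession; accessions that cannot be filled are reported in the
#' panel's shortfall.
#'
#' @param ranked output of [rankCandidates()].
#' @param cap markers per accession (default 2).
#' @param minSeparation minimum distance in bp between selected marker
#'   positions on one chromosome (default 500, i.e. disjoint windows).
#' @return A [MarkerPanel-class].
#' @export
selectPanel <- function(ranked, cap = 2L, minSeparation = 500L) {
  .check(is.list(ranked) && length(ranked) > 0L,
         "ranked candidate lists are required")
  sel <- list()
  sel_chrom <- character(); sel_pos <- integer()
  shortfall <- character()
  for (acc in names(ranked)) {
    taken <- 0L
    tab <- ranked[[acc]]
    for (j in seq_len(nrow(tab))) {
      if (taken >= cap) break
      chrom <- tab$chrom[j]; pos <- tab$pos[j]
      clash <- sel_chrom == chrom & abs(sel_pos - pos) <= minSeparation
      if (any(clash)) next
      sel[[length(sel) + 1L]] <- as.data.frame(tab[j, , drop = FALSE])
      sel_chrom <- c(sel_chrom, chrom); sel_pos <- c(sel_pos, pos)
      taken <- taken + 1L
    }
    if (taken < cap) shortfall <- c(shortfall, acc)
  }
  cols <- c("marker_id", "accession", "chrom", "pos", "ref", "alt",
            "dp", "gq", "effect", "region", "rank", "window_start",
            "window_end", "candidate_sequence")
  m <- if (length(sel)) do.call(rbind, sel) else
    as.data.frame(matrix(nrow = 0, ncol = 0))
  for (cn in setdiff(cols, colnames(m)))
    m[[cn]] <- if (nrow(m)) NA else character(0)
  m <- DataFrame(m[, cols, drop = FALSE])
  rownames(m) <- NULL
  new("MarkerPanel", markers = m, cap = as.integer(cap),
      minSeparation = as.integer(minSeparation),
      shortfall = shortfall)
}
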