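#' Evaluate a marker panel for accession discrimination
#'
#' A marker passes when its target accession's sample is homozygous for
#' the alternative allele while every other core-collection sample is
#' homozygous reference; an accession is identified when at least one of
#' its markers passes. Outgroup samples are expected to be ref-hom (or
#' missing) everywhere; an outgroup alt-hom call flags the marker as
#' non-specific. Unexpected calls are collected in the confusion table.
#'
#' Core membership comes from the call matrix's group labels; when no
#' groups are set, samples whose id matches a panel accession are treated
#' as core and the rest as outgroup.
#'
#' @param panel a [MarkerPanel-class].
#' @param calls a [CallMatrix-class] containing every panel marker and
#'   one sample per core accession (sample id = accession id).
#' @return An [EvaluationReport-class].
#' @export
evaluateDiscrimination <- function(panel, calls) {
  stopifnot(is(panel, "MarkerPanel"), is(calls, "CallMatrix"))
  m <- markers(panel)
  cm <- calls@calls
  absent <- setdiff(m$marker_id, rownames(cm))
  .check(length(absent) == 0L, "marker(s) missing from call matrix: %s",
         paste(absent, collapse = ", "))
  samples <- colnames(cm)
  groups <- calls@groups
  if (all(is.na(groups))) {
    core <- samples %in% m$accession
  } else {
    core <- !is.na(groups) & groups == "core"
  }
  core_samples <- samples[core]
  out_samples <- samples[!core]
  conf <- list()
  n_mk <- nrow(m)
  specific <- logical(n_mk); out_clean <- logical(n_mk)
  target_call <- character(n_mk)
  for (j in seq_len(n_mk)) {
    mk <- m$marker_id[j]; acc <- m$accession[j]
    row <- cm[mk, ]
    tgt <- if (acc %in% samples) row[[acc]] else NA_character_
    target_call[j] <- if (is.null(tgt)) NA_character_ else tgt
    others <- setdiff(core_samples, acc)
    others_ok <- all(row[others] == "ref")
    specific[j] <- identical(tgt, "alt") && others_ok
    bad_others <- others[row[others] != "ref"]
    for (s in bad_others)
      conf[[length(conf) + 1L]] <- data.frame(
        marker_id = mk, sample = s, call = row[[s]],
        expected = "ref", stringsAsFactors = FALSE)
    bad_out <- out_samples[row[out_samples] == "alt"]
    out_clean[j] <- length(bad_out) == 0L
    for (s in bad_out)
      conf[[length(conf) + 1L]] <- data.frame(
        marker_id = mk, sample = s, call = "alt",
        expected = "ref/miss", stringsAsFactors = FALSE)
    if (!identical(tgt, "alt") && acc %in% samples)
      conf[[length(conf) + 1L]] <- data.frame(
        marker_id = mk, sample = acc, call = tgt,
        expected = "alt", stringsAsFactors = FALSE)
  }
  marker_res <- DataFrame(marker_id = m$marker_id,
                          accession = m$accession,
                          target_call = target_call,
                          specific = specific,
                          outgroup_clean = out_clean)
  accs <- unique(m$accession)
  n_pass <- vapply(accs, function(a)
    sum(specific[m$accession == a]), integer(1))
  acc_res <- DataFrame(accession = accs,
                       n_markers = as.integer(table(m$accession)[accs]),
                       n_pass = n_pass,
                       identified = n_pass >= 1L)
  confusion <- if (length(conf)) DataFrame(do.call(rbind, conf)) else
    DataFrame(marker_id = character(), sample = character(),
              call = character(), expected = character())
  new("EvaluationReport",
      markerResults = marker_res,
      accessionResults = acc_res,
      confusion = confusion,
      summary = list(
        n_markers = n_mk,
        n_markers_pass = sum(specific),
        n_accessions = length(accs),
        n_accessions_identified = sum(acc_res$identified),
        n_confusions = nrow(confusion)))
}

#' Test a marker's ability to separate two parents and their F1
#'
#' For a marker specific to one parent, the expected pattern of a true
#' cross is: parent-of-origin alt-hom, the other parent ref-hom, and the
#' F1 heterozygous -- three pairwise-distinct genotype clusters. The
#' verdict fails when the F1 call is anything but het (an alt-hom F1 is
#' the selfed/contaminant signature).
#'
#' @param calls a [CallMatrix-class] whose groups label one sample each
#'   as `parent1`, `parent2` and `F1`, or pass the three sample ids
#'   explicitly.
#' @param marker marker id to test.
#' @param parent1,parent2,f1 optional sample ids overriding the group
#'   labels.
#' @return A list: `pass` (logical), `parent_of_origin` (sample id
#'   carrying the alt allele), `calls` (the three calls), `reason`
#'   (when failing).
#' @export
evaluateF1 <- function(calls, marker, parent1 = NULL, parent2 = NULL,
                       f1 = NULL) {
  stopifnot(is(calls, "CallMatrix"))
  cm <- calls@calls
  .check(marker %in% rownames(cm), "marker %s not in call matrix", marker)
  by_group <- function(label, given) {
    if (!is.null(given)) return(given)
    hit <- names(calls@groups)[!is.na(calls@groups) &
                                 calls@groups == label]
    .check(length(hit) >= 1L, "no sample labelled %s", label)
    hit[1]
  }
  p1 <- by_group("parent1", parent1)
  p2 <- by_group("parent2", parent2)
  fs <- by_group("F1", f1)
  .check(all(c(p1, p2, fs) %in% colnames(cm)),
         "parent/F1 sample(s) missing from call matrix")
  g <- c(parent1 = cm[marker, p1], parent2 = cm[marker, p2],
         F1 = cm[marker, fs])
  if (g[["parent1"]] == "ref" && g[["parent2"]] == "ref")
    stop(sprintf("marker %s not informative: both parents hom-ref",
                 marker), call. = FALSE)
  if (g[["parent1"]] == "alt" && g[["parent2"]] == "alt")
    stop(sprintf("marker %s not informative: both parents hom-alt",
                 marker), call. = FALSE)
  origin <- if (g[["parent1"]] == "alt") p1
            else if (g[["parent2"]] == "alt") p2 else NA_character_
  pass <- !is.na(origin) &&
    sum(g[c("parent1", "parent2")] == "ref") == 1L &&
    g[["F1"]] == "het"
  reason <- if (pass) NA_character_
    else if (is.na(origin)) "no parent is hom-alt"
    else if (g[["F1"]] == "alt") "F1 hom-alt (selfed/contaminant signature)"
    else if (g[["F1"]] != "het") sprintf("F1 call is %s", g[["F1"]])
    else "parents not hom-alt/hom-ref"
  list(pass = pass, parent_of_origin = origin, calls = g, reason = reason)
}

#' Assess seed-lot purity at one marker
#'
#' Purity is the proportion of non-missing seed genotypes matching the
#' expected call (het for an F1 lot where the parents differ). Missing
#' calls are excluded from the denominator and counted separately;
#' non-matching seeds are listed as off-types with their calls.
#'
#' @param expected the expected call: `"ref"`, `"het"` or `"alt"`.
#' @param seedlotCalls named character vector of seed calls
#'   (`ref`/`het`/`alt`/`miss`).
#' @return A list: `purity` (proportion in [0,1], NA when every call is
#'   missing), `n_tested`, `n_missing`, `offTypes` (named character
#'   vector of non-matching calls).
#' @export
assessPurity <- function(expected, seedlotCalls) {
  .check(length(seedlotCalls) > 0L, "empty seed lot")
  .check(expected %in% c("ref", "het", "alt"),
         "expected call must be ref, het or alt")
  .check(all(seedlotCalls %in% .CALL_LEVELS),
         "seed calls must be one of %s", paste(.CALL_LEVELS,
                                               collapse = "/"))
  if (is.null(names(seedlotCalls)))
    names(seedlotCalls) <- sprintf("seed%03d", seq_along(seedlotCalls))
  miss <- seedlotCalls == "miss"
  tested <- seedlotCalls[!miss]
  off <- tested[tested != expected]
  list(purity = if (length(tested)) mean(tested == expected) else
         NA_real_,
       n_tested = length(tested),
       n_missing = sum(miss),
       offTypes = off)
}
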