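---
title: "Designing accession-specific KASP markers with kaspTools"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Designing accession-specific KASP markers with kaspTools}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(kaspTools)
```

## The model

A KASP assay genotypes one biallelic SNP with two allele-specific
forward primers and a common reverse primer; its design input is a
target sequence with the SNP bracketed as `[REF/ALT]`. For a marker to
identify one accession inside a germplasm collection, the assay's SNP
must satisfy a population-genetic condition and a sequence condition.

The population-genetic condition is *specificity*: at the site, the
target accession is homozygous for the alternative allele and every
other accession is homozygous reference. kaspTools assumes the panel
consists of inbred or doubled-haploid lines, which is why heterozygous
calls are treated as noise (blanked during filtering) rather than as
genotypes: a residual-heterozygosity call in such material is far more
often a mapping or calling artefact than a true heterozygote. Panels
with genuinely heterozygous material can keep hets
(`homozygousOnly = FALSE`) for *evaluation*, but specificity calling
requires the homozygous-only matrix.

The sequence condition is that the 501-bp window centred on the SNP
must amplify uniquely and bind primers on non-polymorphic sequence.
Four screens implement it: no reference Ns, no genome-wide sequence
redundancy, no repeat overlap, no segregating indel in the window.

## Tunable parameters

| parameter | default | meaning |
|---|---|---|
| `minDepth` | 3 | genotype read depth must be **strictly greater** (DP ≥ 4 survives) |
| `minGQ` | 30 | genotype quality must be strictly greater (GQ ≥ 31 survives) |
| `maxMissingOthers` | 0 | tolerated fraction of missing calls among non-target accessions |
| flank | 250 bp | window = pos ± 250 → 501 bp, SNP at position 251 |
| `maskThreshold` | 0.10 | mask positions with non-reference fraction strictly above this |
| `minDuplicateMatch` | 100 bp | exact repeated substring length that defines redundancy |
| `shortlist` | 5 | candidates ranked per accession before selection |
| `cap` | 2 | markers selected per accession |
| `minSeparation` | 500 bp | selected markers closer than this on one chromosome are considered overlapping |

The depth/GQ bounds are deliberately strict inequalities — the
filtering rule is quoted as "read depth > 3, genotype quality > 30",
so DP 3 and GQ 30 fail. Both are configurable for users whose calling
pipeline uses different conventions.

`maxMissingOthers = 0` is the conservative default: a missing genotype
in a non-target accession could hide a shared alternative allele, so by
default it disqualifies the site. Raising the tolerance trades marker
yield against the risk of non-specific markers; with 50-accession
panels and deep resequencing the strict policy already yields thousands
of candidates genome-wide.

The masking rule is applied per window position over all accessions:
the fraction counting *both* alternative alleles and unknown bases
(missing or het genotypes — "missing or alternative") is compared
strictly against 10%. Position 251 itself is exempt: the target SNP is
variable by definition (1/50 = 2% in the intended population, but the
exemption keeps the rule safe for small panels where one carrier would
exceed the threshold).

## Design choices where the design was open

**Redundancy screen.** The reference approach for flank uniqueness is a
BLAST-style megablast search with unpublished cutoffs. kaspTools
instead defines redundancy exactly: a window fails iff some substring
of length ≥ `minDuplicateMatch` (100 bp) occurs at a second genomic
locus on either strand. Such a repeat exists iff some 100-mer occurs
twice genome-wide, so the implementation builds one table of
strand-canonical 100-mers seen more than once (`genomeDuplicateIndex()`)
and intersects each window with it. This is deterministic,
dependency-free, and verified in the test suite against a naive
string-search oracle on ≤ 100-kb genomes. It is a *proxy*: megablast
would additionally catch high-identity inexact repeats; users needing
that behaviour can screen candidate TSVs with an external aligner and
drop hits before `selectPanel()`.

**Positional alignment instead of multiple alignment.** Per-accession
flanks are reconstructed by substituting each accession's hom-alt SNVs
into the reference window, so all flanks are positionally aligned by
construction and a gapped multiple alignment (ClustalW in the original
workflow) is unnecessary — it is only needed when indels are present,
and windows containing any segregating indel are dropped outright
(`indel-in-window`), because an indel under a primer defeats the assay
anyway. This removes a heavy nondeterministic dependency; the dropped
windows are reported in the drop log.

**Reconstruction from genotype calls, not read pileups.** Flanks could
be rebuilt from per-accession BAMs; kaspTools rebuilds them from the
genotype matrix it already has. Missing genotypes leave the reference
base in the reconstructed sequence but are tallied separately and fed
into the masking fraction, so the "missing or alternative" rule is
honoured without inventing sequence.

**Severity order for effect annotation.** When features overlap, one
label must win. The fixed order (stop-gained > start-lost > stop-lost >
splice-acceptor > splice-donor > non-synonymous > stop-retained >
synonymous > intron > upstream > downstream > intergenic) mirrors the
impact tiers of standard annotators (high > moderate > low > modifier).
Splice sites are the two intronic bases flanking each junction;
upstream/downstream windows are 5,000 bp from the gene span,
strand-aware; a SNP upstream of one gene and downstream of another is
upstream. Exonic positions outside the CDS (UTR segments) have no
category of their own in the twelve-label vocabulary and are reported
as gene-interior non-coding (`intron`); the simulator never generates
UTRs, so tests pin only the published categories. One transcript per
gene is assumed.

**Greedy panel selection.** "Positions unique to the accessions" is
operationalized as window-level disjointness (same-chromosome markers
must be > 500 bp apart), because overlapping amplicons — not merely
identical coordinates — are the failure mode in pooled assays. The
sweep is greedy in accession order then rank order; no optimization
objective is published, and greedy selection is deterministic,
order-stable, and in practice leaves no shortfall when each accession
has two clean candidates.

**Ranking ties.** Within an accession: exonic candidates first (genic
regions are better conserved across germplasm, so primer sites are more
transferable), then depth descending, then GQ descending, then
chromosome/position ascending. The final positional tie-break makes the
whole pipeline a total order: identical inputs give byte-identical
panels.

## What the simulator emulates — and what it does not

`simulateKaspData()` emulates the *decision structure* of a
resequencing panel: a uniform-random genome, embedded two-exon ORFs on
both strands, annotated repeats, an optional duplicated segment,
N-patches, and a joint-called VCF in which each planted variant either
satisfies the accession-specific definition cleanly or violates exactly
one rule (shared carrier, het call, multi-allelic site, DP = 3,
GQ = 30, repeat overlap, duplicated flank, chromosome edge, reference
Ns, indel in window). Clean planted SNPs are pairwise separated by more
than 500 bp with DP 12 / GQ 60, the stated panel being 50 accessions
with five clean SNPs each — enough for every accession to fill its
two-marker cap.

It does **not** emulate: linkage disequilibrium or demographic
structure; base-composition bias (the i.i.d. uniform background is what
makes the redundancy screen's negative examples sound — a chance
repeated 100-mer has probability < 10⁻⁴⁰ at these scales); sequencing
error models (DP/GQ are planted constants, with boundary values only at
designated confounders); indels beyond the indel-in-window confounder;
multi-isoform genes or UTRs. A green end-to-end test therefore
establishes that the pipeline implements its stated rules exactly — not
that those rules are sufficient for any particular real genome. On real
data the binding constraint is usually repeat content and paralogy,
which enter here only through the annotation track and the duplicate
screen.

## Numerical and degenerate-input conventions

* Coordinates are 1-based inclusive at every interface (VCF/GFF3
  convention); BED output converts at the boundary.
* A single shared base counts as repeat overlap (inclusive intervals).
* Absent DP/GQ annotations fail the corresponding filter
  (conservative).
* Genes whose CDS length is not a codon multiple after phase adjustment
  warn and yield positional labels only.
* Sites within 250 bp of a chromosome end are rejected with reason
  `edge`; an empty candidate set produces an empty panel, not an error.
* All randomness in the simulator flows from one `set.seed(seed)`;
  outputs are byte-identical across runs for a fixed seed.

## Known limitations

* Exact-substring redundancy is blind to diverged paralogs
  (see above).
* One transcript per gene; no UTR-specific effect categories.
* The purity statistic is a plain matching fraction with missing calls
  excluded from the denominator; no confidence interval is attached
  (none is published for the assay this reproduces).
* Fluorescence-to-genotype clustering happens on the KASP instrument;
  kaspTools consumes discrete calls and cannot diagnose poor cluster
  separation.
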