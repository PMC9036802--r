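# kaspTools

Design and evaluation of accession-specific KASP genotyping markers from
population resequencing data.

## The problem

Commercial vegetable seed is mostly F1 hybrid seed, and suppliers must
verify that a seed lot is what its label says: pure parental stocks, and
hybrid seed that is actually the intended cross. Field grow-out tests are
slow and subjective; Kompetitive Allele Specific PCR (KASP) assays
replace them with a fluorescence-based read-out of a single diagnostic
SNP. The catch is finding SNPs that are *diagnostic*: present (as a
homozygous alternative allele) in exactly one accession of a germplasm
collection and absent from all others, sitting in sequence that a primer
can target uniquely.

kaspTools implements that search as a pipeline over a joint-called
multi-sample VCF, a reference genome, and gene/repeat annotations:

1. **Genotype filtering** — a genotype survives only with read depth
   > 3 and genotype quality > 30; heterozygous calls are blanked
   (inbred/doubled-haploid panels should be homozygous); multi-allelic
   sites are removed.
2. **Specificity calling** — a site is accession-specific when exactly
   one accession is hom-alt and every other accession is an explicit
   hom-ref call (missing-call tolerance is configurable).
3. **Flank screening** — the 501-bp window centred on the SNP
   (position 251) is rejected if it contains reference Ns, shares an
   exact substring of ≥ 100 bp with a second genomic locus on either
   strand (redundancy → off-target amplification), overlaps an annotated
   repeat, or is touched by an indel segregating in the population.
4. **Effect annotation** — each SNP gets one of twelve categories
   (synonymous, non-synonymous, stop-gained, …, intergenic) from
   strand-aware codon evaluation against the gene models.
5. **Consensus masking** — per-accession flanks are reconstructed from
   the genotype matrix; any window position where more than 10% of
   accessions carry a non-reference or unknown base is masked with N so
   primers avoid polymorphic sites. The deliverable per marker is the
   masked 501-bp sequence with the target SNP bracketed, e.g.
   `...AGCTAAGT[C/G]CCCCTGGA...`.
6. **Panel selection** — within each accession candidates are ranked
   (exonic first, then depth, then GQ), shortlisted to five, and a
   greedy sweep picks two markers per accession whose windows never
   overlap another selected marker's window.
7. **Evaluation** — given discrete KASP calls, the package scores
   per-marker specificity, per-accession identification,
   parent/F1 discrimination (the F1 must be heterozygous), and seed-lot
   purity (matching fraction of non-missing calls).

A simulator (`simulateKaspData()`) generates reference genomes, gene and
repeat annotations, and population VCFs with planted ground truth —
including confounders that each violate exactly one pipeline rule — so
the whole pipeline is testable without any external data.

## Worked example

The package ships the published eight-accession validation matrix
(16 SNPs × 8 *Brassica rapa* accessions) as `table3Fixture()`:

```r
library(kaspTools)
snps <- callAccessionSpecific(filterGenotypes(table3Fixture()))
table(snps$accession)
#>     26021     26022     28059     28061 CNU_11411 CNU_11412 CNU_11479 CNU_11480
#>         2         2         2         2         2         2         2         2
```

Each accession is recovered with exactly its two diagnostic SNPs; for
example A07:20,012,970 (G→A) is attributed to CNU_11411 — the marker
(`A07_20012970`) used to separate parents and F1 hybrids.

End-to-end on simulated data:

```r
sim <- simulateKaspData(seed = 1, nAccessions = 10, nChromosomes = 2,
                        chromLength = 60000, specificPerAccession = 3)
genome <- readReference(sim$fasta)
gd     <- readPopulationVcf(sim$vcf)
res    <- runKaspPipeline(gd, genome, genes = sim$genes,
                          repeats = sim$repeats)
res$panel
#> MarkerPanel: 20 markers over 10 accessions (cap 2)

calls <- truthCallMatrix(res$panel, extraSamples = sprintf("OUT%02d", 1:5))
evaluateDiscrimination(res$panel, calls)
#> EvaluationReport
#>   n_markers: 20
#>   n_markers_pass: 20
#>   n_accessions: 10
#>   n_accessions_identified: 10
#>   n_confusions: 0
```

Ten accessions, two non-overlapping markers each, all specific against
the core panel and a clean outgroup.

A thin command-line wrapper over the same functions is installed at
`inst/exec/kasptools` (subcommands `simulate`, `detect`, `design`,
`select`, `evaluate`, `purity`).

## Acceptance script

`scripts/acceptance.R` re-runs the pipeline's headline computation from
scratch: it simulates the default 50-accession population (five clean
accession-specific SNPs per accession, no confounders), executes
filtering, specificity calling, flank design and panel selection at the
default two-markers-per-accession cap, and reports the resulting panel
size as JSON.

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```

## Vignette

`vignettes/kasp-marker-design.Rmd` documents the model and its
assumptions, every tunable threshold with its default and rationale,
what the simulator does and does not emulate, and known limitations.
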