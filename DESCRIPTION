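Package: kaspTools
Title: Accession-Specific SNP Detection and KASP Marker Panel Design
Version: 0.99.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Builds Kompetitive Allele Specific PCR (KASP) marker panels
    from multi-accession resequencing data. Starting from a joint-called
    multi-sample VCF and a reference genome, the package filters genotypes
    on read depth and genotype quality, identifies accession-specific SNPs
    (sites homozygous for the alternative allele in exactly one accession),
    screens 501-bp flanking windows for reference gaps, genome-wide sequence
    redundancy and repeat overlap, annotates variant effects against gene
    models, builds polymorphism-masked consensus sequences with the target
    variant bracketed at position 251, selects a non-redundant panel of up
    to two markers per accession, and evaluates panels for accession
    discrimination, F1 hybrid identification and seed-lot purity. A
    simulator generates reference genomes, annotations and population VCFs
    with planted ground truth for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3.0)
Imports:
    methods,
    stats,
    utils,
    BiocGenerics,
    S4Vectors,
    IRanges,
    GenomicRanges,
    GenomeInfoDb,
    Biostrings,
    SummarizedExperiment,
    VariantAnnotation,
    rtracklayer,
    data.table
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
biocViews: Genetics, SNP, VariantAnnotation, Sequencing
RoxygenNote: 7.3.3
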