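Package: modscreen
Title: Analysis of Whole-Genome-Sequenced Modifier Screens in C. elegans
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools for analysing forward-genetic modifier screens resolved by
    whole-genome sequencing. Per-strain variant sets are cleaned by parental
    background subtraction, annotated for coding effect against gene models
    and a reference genome, and summarised into a gene-by-strain hit
    incidence matrix. Recurrently hit genes are scored with a binomial
    probability of chance recurrence calibrated by per-gene hit counts from
    a mutagenized reference panel (the Million Mutation Project style of
    mutability estimate). Companion calculators cover screen sizing
    (haploid genomes screened, expected detections under an EMS forward
    mutation rate), taspase cleavage-motif scanning of proteomes, and the
    statistics used for embryo quantitation (batch-normalized fluorescence
    intensities, rank-sum tests, boxplot notch widths, gut-granule
    proportions, and smFISH transcript-ratio comparisons). A synthetic
    screen simulator generates genomes, gene models, EMS-spectrum variant
    sets with injected recurrent modifiers, and quantitation tables with
    recorded ground truth for validation.
License: MIT
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
    Biostrings,
    SummarizedExperiment,
    VariantAnnotation,
    rtracklayer,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
biocViews: Genetics, VariantAnnotation, Sequencing, Software
Config/testthat/edition: 3
RoxygenNote: 7.3.3
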