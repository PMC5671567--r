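Package: hweqc
Title: Directional Hardy-Weinberg Departure Testing for Genotype Quality Control
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tests genotype count distributions for departure from
    Hardy-Weinberg equilibrium and classifies departures by direction:
    loss of heterozygosity (LoH), typical of deletion polymorphisms,
    population stratification and inbreeding, versus gain of
    heterozygosity (GoH), typical of genotyping error such as paralog
    cross-hybridization and indel miscalls. Provides the variant
    inclusion filters and five per-variant explanatory features used to
    characterize each class, group-comparison machinery contrasting
    departing variants against in-equilibrium controls, genomic region
    scans that detect clustered departures (deletion LoH blocks, paralog
    GoH peaks), and synthetic cohort generators embodying each causal
    mechanism with ground-truth labels.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    vcfR,
    GenomicRanges,
    IRanges,
    S4Vectors
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
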