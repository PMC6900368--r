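Package: kindredscope
Title: Kindred Analysis for Familial Hypercholesterolemia Genomics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for the kindred-level genetic analysis of severe
    hypercholesterolemia: prioritization of rare candidate variants from
    annotated exome tables (consequence, read-depth, candidate-gene and
    allele-frequency filters with a damaging-call exception and
    multi-predictor consensus ranking), cosegregation search over pedigrees
    under dominant, recessive and compound-heterozygous models using lipid
    phenotypes, characterization of structural-variant deletion junctions
    (length, non-templated insert, microhomology) with an in-silico
    multiplex PCR screening assay, and population-of-origin inference for
    phased haplotype blocks against an allele-frequency reference panel
    (panel QC, windowed LD pruning, PCA projection, smoothed per-site
    likelihoods with softmax posteriors). A synthetic-data generator
    produces reference panels under the Balding-Nichols model, Mendelian
    pedigrees with planted causal alleles, genotype-dose lipid phenotypes
    and allele sequences with embedded primer sites, so the whole pipeline
    is testable without protected patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite,
    yaml,
    vcfR,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
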