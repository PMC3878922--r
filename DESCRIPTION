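Package: cloneCNV
Title: De Novo CNV and Copy-Neutral LOH Discovery and Validation in Cloned Genomes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Discovery and multi-platform validation of de novo copy number
    variants (CNVs) and copy-neutral loss of heterozygosity (LOH) in cloned
    genomes profiled against their nuclear donor. Implements rank-based
    recursive segmentation of array-CGH log2 ratios with threshold-based CNV
    calling, dye-swap concordance validation, SNP-array quality control and
    B-allele-frequency allelic-imbalance / copy-neutral LOH detection,
    multi-point qPCR 2^-ddCt relative copy-number validation of CNV existence
    and boundaries, permutation-based interval overlap enrichment against
    known-CNV databases, segmental-duplication and repeat-class context
    profiling, and multilocus microsatellite probability of identity under
    Hardy-Weinberg and full-sibling models. Includes seeded synthetic-data
    generators for donor/clone aCGH, dye-swap, SNP-array, qPCR, annotation
    and microsatellite data with ground-truth event lists.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    GenomicRanges,
    IRanges,
    S4Vectors
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
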