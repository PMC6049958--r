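Package: tetrascan
Title: Population-Genomic Scans, Introgression Statistics and QTL Mapping
    for Autotetraploids
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for population genomics of autotetraploid plants with an
    outgroup: polarized allele-frequency estimation from tetraploid genotype
    calls, fixed-SNP-count windowed scans of differentiation (G_ST) and
    site-frequency-spectrum statistics (Tajima's D, Fay and Wu's H),
    ABBA-BABA introgression estimators (Patterson's D, f_hom, f_d) with
    block-jackknife errors and a gene-level candidate-calling rule,
    bulked-segregant F2 mapping with LOD model selection and permutation
    thresholds, expression classification by post-hoc Tukey contrasts with a
    flowering-time correlation scan, tetraploid Hardy-Weinberg arithmetic,
    and synthetic-data generators with known truth for all of the above.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr (>= 1.1.0),
    tidyr,
    tibble,
    purrr,
    readr,
    stringr,
    rlang,
    generics,
    ggplot2,
    vcfR,
    rtracklayer,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    DESeq2,
    jsonlite,
    knitr,
    rmarkdown
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
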