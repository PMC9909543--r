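Package: bulkmapr
Title: Mapping-by-Sequencing Workflows for Bulked Segregant and Backcross
    Designs
Version: 1.0.0
Authors@R:
    person("Package", "Author", , "author@example.org", role = c("aut", "cre"))
Description: Variant-density mapping for recurrent-backcross populations,
    QTL-seq scanning of two phenotypically opposite bulks, a simplified
    allele-frequency linkage mapper, and a variant-effect analyzer with
    genotyping-primer design, all operating on standard FASTA, GFF3 and
    VCF inputs.  Includes a mapping-population simulator (EMS mutagenesis,
    recombination under the Haldane map function, phenotypic selection of
    bulks, binomial read-depth sampling) that emits standard files so
    every workflow can be exercised without external data.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Biostrings,
    BiocGenerics,
    GenomeInfoDb,
    GenomicRanges,
    IRanges,
    S4Vectors,
    SummarizedExperiment,
    VariantAnnotation,
    rtracklayer,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
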