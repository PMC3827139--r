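Package: haplomosaic
Title: Simulation and Analysis of DNA Polymorphism Density, Haplotype
    Mosaics and Genetic Maps in Inbred Crop Genomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for studying the density and distribution of DNA
    polymorphism in inbred crop genomes such as grain sorghum. Includes a
    forward simulator of annotated genomes, founder panels, pedigrees and
    recombinant inbred line (RIL) populations with known truth; in-silico
    prediction of restriction-site genotyping-by-sequencing tags for a
    methylation-sensitive enzyme, with simulated tag recovery and windowed
    methylation profiling; classification of variants by genomic context
    and coding consequence with windowed, per-gene and regional density
    profiles and zero-depth large-deletion detection; pedigree haplotype
    tracing with identity-by-descent segment detection; Kosambi genetic-map
    construction with LOD filtering; and UPGMA dendrograms from marker-based
    nucleotide distances with bootstrap support.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    tibble,
    dplyr,
    tidyr,
    purrr,
    readr,
    rlang,
    ggplot2,
    generics,
    yaml,
    stats,
    tools,
    utils,
    methods,
    ape,
    vcfR,
    Biostrings,
    IRanges,
    GenomicRanges,
    rtracklayer
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr,
    jsonlite
Config/testthat/edition: 3
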