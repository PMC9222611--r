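Package: orgvar
Title: Intraspecific Variation Analysis for Plant Organelle Genomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Genome-wide analysis of intraspecific variation in plant
    mitochondrial and plastid genomes. Partitions every genomic position into
    functional categories (with codon-degeneracy classification of coding
    sites into synonymous and nonsynonymous site classes), applies GATK-style
    hard filters to population variant calls, summarises SNP and indel
    abundance, transition/transversion ratios and minor allele frequencies per
    category, stratifies plastid statistics by LSC/SSC/IR structural region,
    and profiles copy number from windowed sequencing depth. Includes a
    synthetic-data generator producing annotated circular genomes, population
    VCFs with category-specific mutation rates, and per-site depth tables with
    implanted copy-number segments, so the whole pipeline runs and is testable
    without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    rtracklayer,
    stringr,
    tibble,
    tidyr,
    vcfR,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
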