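Package: radanchor
Title: Linkage-Map-Guided Genome Anchoring and QTL Mapping for ddRAD-Seq F2 Crosses
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for turning a fragmented plant genome assembly plus a
    ddRAD-seq F2 genotyping experiment into sex-filtered scaffolds, a
    genetic linkage map, chromosome pseudomolecules and QTL calls.
    Includes male/female read-depth screening for Y-linked scaffolds,
    a two-tier SNP site-filter cascade with parental/F1 genotype
    filtering and 1:2:1 segregation testing, EM estimation of F2
    recombination fractions with linkage grouping and marker ordering,
    chimeric-scaffold detection and splitting against the map,
    AGP/FASTA pseudomolecule emission with fixed N gaps, Haley-Knott
    and composite interval mapping with permutation thresholds and
    LOD-support intervals, evidence-based gene confidence
    classification, and a synthetic-data generator with known ground
    truth for end-to-end validation.
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
    igraph,
    jsonlite,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    vcfR
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
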