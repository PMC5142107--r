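Package: varcascade
Title: Variant Prioritization, Segregation and Splice Consequences for
    Recessive Disease Exome Studies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for family-based rare-disease exome analysis: a four-step
    variant filtering cascade (population allele-frequency filtering, X-linked
    screening, autosomal recessive candidate selection, and cross-family gene
    intersection) with coverage-gap reporting and a singleton-heterozygote
    rescue step; pedigree segregation tests for homozygous and compound
    heterozygous inheritance with phase inference under partial parental
    genotyping; transcript-coordinate arithmetic that parses HGVS c. variants,
    simulates aberrant splicing events (exon skipping, intron retention,
    cryptic splice sites) and emits protein-level HGVS consequences; a
    synthetic multi-family cohort generator (VCF, PED, annotation tables and
    coverage masks) with planted causal configurations for end-to-end
    testing; and lightweight comparative-sequence utilities (global pairwise
    alignment and alignment-column conservation).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    jsonlite,
    methods,
    stats,
    utils,
    vcfR
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
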