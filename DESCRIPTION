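Package: pgxbench
Title: Targeted Pharmacogenomic Panel Construction and Benchmarking
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for evaluating targeted pharmacogenomic (PGx) long-read
    sequencing experiments that use adaptive sampling enrichment. Builds an
    adaptive-sampling target panel (BED) from clinical variant annotations and
    gene coordinates, benchmarks a query callset against a truth callset
    restricted to the panel variants (recall, precision, and a true-negative
    inclusive accuracy), scores per-gene haplotype phasing concordance against
    truth haplotypes, classifies star-allele diplotype calls against reference
    calls (identical, augmenting, incorrect, or no reference), and summarises
    read filters and on-target depth. A synthetic-data module generates
    genomes, panels, phased truth and corrupted query callsets, depth tracks
    and read summaries with known error rates, so every stage is testable
    end to end with parameter-recovery checks.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer,
    vcfR,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
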