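Package: viromeflow
Title: Mosquito RNA Virome Profiling, Food-Source Assignment and
    Co-Occurrence Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Downstream analysis of bulk RNA viromes from field-collected
    mosquitoes, starting from tabular alignment-hit files, contig sequences
    and read-mapping summaries. Implements candidate virus selection with
    database-specific e-value cutoffs, false-positive removal against host
    and general databases, CD-HIT-style greedy clustering of RdRp contigs
    into virus operational taxonomic units, novelty and completeness calls,
    RPM abundance normalisation, Shannon diversity with binomial
    downsampling, last-common-ancestor assignment of bloodmeal and plant
    food sources, hypergeometric virus-food co-occurrence tests, and
    cross-group virome-sharing summaries. A seeded synthetic-data generator
    with planted ground truth supports end-to-end testing without access to
    raw sequencing data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    Biostrings
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
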