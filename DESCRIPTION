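Package: hmcscan
Title: Gene-Body 5-Hydroxymethylcytosine Enrichment Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Downstream analysis of 5-hydroxymethylcytosine (5hmC)
    capture sequencing across tissues: SICER-style window-clustering
    island calling against input controls, per-gene intragenic coverage
    fractions and coverage classes, scaled metagene profiles around gene
    bodies, TMM-normalised log2 counts-per-million expression, sample
    similarity by Spearman correlation, hierarchical clustering of
    gene-body enrichment patterns into coverage-ordered clusters,
    organ- and sex-specific gene calling, and the two exception classes
    of the coverage-expression association. Ships a fully parameterised
    synthetic study generator (toy genome, annotation, peak sets,
    fragments, and negative-binomial counts with planted structure) so
    every stage is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    GenomicRanges,
    IRanges,
    S4Vectors,
    GenomeInfoDb,
    rtracklayer,
    data.table,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    edgeR,
    jsonlite,
    withr
Config/testthat/edition: 3
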