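Package: homeodose
Title: Homeolog Allele Dosage, Expression and Growth Analysis for Polyploids
Version: 0.1.0
Authors@R:
    person("Package", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for quantifying a segregating small deletion among the
    homeologous gene copies of a polyploid from raw sequencing reads.
    Designs paralog-unique, allele-discriminating probe pairs around a
    variant site, counts exact probe matches in FASTQ/FASTA reads on both
    strands, infers the deletion-allele dosage by binomial maximum
    likelihood with chi-square goodness-of-fit tests over copy
    configurations, and predicts the protein consequence of a frameshift
    deletion. Also provides FPKM-based expression filtering and
    two-condition set-partition summaries, group fold-change estimation,
    a two-stage logistic growth-curve analysis for plant height series,
    and seeded synthetic-data generators (homeologous references, reads,
    clone sets, negative-binomial count matrices, growth trajectories)
    so that every stage of the pipeline can be exercised and validated
    without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    jsonlite,
    optparse,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
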