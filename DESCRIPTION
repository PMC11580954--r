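Package: txmend
Title: Cell-Specific Transcript Meta-Assembly from Fragmented Single-Cell Assemblies
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Merges fragmented per-cell transcript assemblies from short-read
    single-cell RNA-seq into candidate full-length transcripts. Builds a
    directed transcript fragment graph over intron chains pooled across cells,
    searches it with a bottleneck-junction dynamic program that maximises a
    merging score, and scores every (candidate, cell) pair with two random
    forest models - a path-level filter and a cell-specific probability model -
    to emit accurate per-cell GTF assemblies. Includes an intron-chain
    evaluation module (precision, adjusted precision, precision-recall curves)
    and a synthetic dropout simulator for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    data.table,
    igraph,
    ranger,
    rtracklayer,
    GenomicRanges,
    S4Vectors,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    pROC,
    optparse,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
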