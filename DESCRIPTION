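Package: metapart
Title: Partitioning Host and Symbiont Transcripts in Mixed
    Meta-Transcriptome Assemblies
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for separating host and microbial symbiont transcripts in
    de novo assemblies of non-sterile plant RNA-Seq, as encountered in
    conifer phyllosphere studies. Implements per-transcript GC-content and
    length statistics (N50), FPKM quantification with the floored-log2
    transform, the tau expression-specificity index with Welch comparison of
    score distributions, top-hit taxonomic assignment with a genome-alignment
    rescue rule, a GC read-pair enrichment filter, a cross-sample exact
    k-mer identity filter, and identity-based single-linkage homolog
    clustering with pooled per-cluster expression. A seeded synthetic-data
    generator emulates the dual-population (plant-like and fungus-like)
    structure of such data with ground truth, so the full pipeline is
    testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    Biostrings,
    data.table,
    igraph,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    mclust,
    withr
Config/testthat/edition: 3
Collate:
    'AllGenerics.R'
    'AllClasses.R'
    'utils.R'
    'seqstats.R'
    'specificity.R'
    'taxonomy.R'
    'synthetic.R'
    'enrichment.R'
    'cluster.R'
    'io.R'
    'pipeline.R'
    'metapart-package.R'
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
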