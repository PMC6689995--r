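Package: atlasforge
Title: Multi-Pass Transcript Quantification and Co-Expression Atlas Construction
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for building a tissue gene-expression atlas from RNA-Seq
    the way large livestock atlas projects do: a simplified pseudoalignment
    quantifier (k-mer transcript index, equivalence-class read assignment,
    EM abundance estimation, TPM output), iterative multi-pass revision of
    the transcript index (removal of unexpressed and low-quality models,
    integration of validated novel transcript models), rule-based validation
    of candidate protein-coding models from per-exon longest-ORF chains and
    filtered homology alignments, Pearson co-expression network construction
    with Markov clustering, and atlas-level summaries (tissue detection
    breadth, cluster expression profiles, tissue-specificity labels). A
    synthetic-data module generates toy genomes, transcript models, planted
    co-expression structure, stranded read pairs and homology tables so the
    whole pipeline is testable end to end without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    Biostrings,
    IRanges,
    GenomicRanges,
    S4Vectors,
    SummarizedExperiment,
    data.table,
    igraph,
    jsonlite,
    mclust
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
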