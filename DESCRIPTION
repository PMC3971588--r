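Package: paleodup
Title: Expression and Sequence Divergence of Ancient Whole-Genome-Duplication Paralogs
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for expression-level divergence between paralog
    pairs retained from an ancient whole-genome duplication. Calls strictly
    duplicated pairs from synteny anchor tables against two outgroup genomes,
    normalizes RNA-seq counts (RPKM and upper-quartile), tests per-pair
    per-tissue differential expression with a log-ratio t-test and
    Benjamini-Hochberg correction, detects tissue-specific reciprocal
    silencing, fits per-pair negative-binomial generalized linear models with
    gene, tissue and gene-by-tissue contrasts to classify pairs into exclusive
    effect categories and detect complementary expression, computes
    Nei-Gojobori dN/dS with Jukes-Cantor correction, and compares categories
    downstream (rank-sum tests, positional binomial tests). A synthetic-data
    module generates count matrices, codon alignments and toy synteny fixtures
    with planted ground truth so every stage is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    MASS,
    Biostrings,
    jsonlite
Suggests:
    rtracklayer,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
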