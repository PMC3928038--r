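Package: trescan
Title: Response-Element Grammar Scanning and Genomic Context Analysis
    for Thyroid Hormone Receptor ChIP Peaks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Genome-wide analysis of thyroid hormone receptor (TRbeta)
    ChIP binding peaks. Compiles and scans IUPAC half-site and dyad
    (direct/everted/inverted repeat) response-element grammars
    bidirectionally over DNA, computes length-normalized occurrence
    rates and fold enrichment of motifs in peak sets against a genomic
    background, derives position frequency matrices and IUPAC consensus
    sequences from top-ranked peaks with log-odds PWM scanning,
    classifies peaks into genomic feature classes with enrichment
    versus genomic representation and TSS-relative frequency profiles,
    links peaks to hormone-regulated gene classes at fixed TSS distance
    cutoffs, and ships a seeded synthetic-study generator (genome, gene
    models, planted response elements, condition-labelled peak sets,
    expression matrix) so the whole pipeline runs without external
    data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    IRanges,
    S4Vectors,
    limma,
    jsonlite,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
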