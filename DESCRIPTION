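Package: rpoNscan
Title: Sigma-54 Regulon Contrasts, Promoter Scanning and Bypass-Transcription Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Genome-wide analysis of sigma-54 (RpoN) dependent transcription
    from a three-strain RNA-seq design: wild-type rpoN, an activator-bypass
    allele lacking Region I (rpoN-dRI), and an rpoN deletion. Implements RPKM
    quantification, per-contrast MA statistics, one-way ANOVA across strains,
    rule-based regulatory categorisation of genes (Region-I-dependent, bypass,
    sigma-54-repressed, unchanged), consensus scanning for sigma-54 -24/-12
    and sigma-70 -35/-10 promoter elements with -12 C conservation scoring,
    positional classification of repressive sigma-54 sites relative to active
    sigma-70 promoters (classes I-IV), and a negative-binomial synthetic-data
    generator with planted ground truth for end-to-end validation.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    rtracklayer,
    stats,
    tools,
    utils,
    yaml
Suggests:
    optparse,
    withr,
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
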