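Package: cryptorf
Title: Integrative Nomination of Cancer-Dependency Cryptic ORFs Encoded by lncRNAs
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An integrative functional-genomics pipeline that nominates
    cancer-dependency cryptic open reading frames (ORFs) encoded by long
    noncoding RNAs. Starting from ribosome-profiling P-site counts it scores
    3-nt periodicity evidence of translation for ATG ORFs, de-duplicates
    highly similar ORFs, calls fitness hits from pooled CRISPR/Cas9 screen
    sgRNA depletion against a negative-control empirical null, filters by
    tumor-versus-normal differential expression and survival association,
    maps bait-specific AP-MS interactors, and triages final targets by
    co-regulation, common factor binding within a strand-aware TSS window,
    and cell-line dependency scores. A seeded synthetic-data module generates
    every input with planted ground truth so the whole pipeline is testable
    without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    Biostrings,
    IRanges,
    S4Vectors,
    survival,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
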