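Package: synorth
Title: Synteny-Restricted Search for Orthologues of Long Noncoding RNAs
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Finds candidate orthologues of (possibly unannotated) long
    noncoding RNAs in a subject genome by restricting a sensitive local
    alignment search to syntenic regions obtained by lifting query
    coordinates through UCSC chain files. Spurious high-scoring segment
    pairs are removed with an empirical right-sided test against a
    per-query background of alignment scores on shuffled genomic ranges,
    with Benjamini-Hochberg control of the false discovery rate.
    Surviving segments are linked into collinear chains by dynamic
    programming, the best chain per query is selected, and every query is
    assigned a conservation status. Includes a self-consistent synthetic
    fixture generator, an optional gene-annotation step, and a
    benchmarking module with confusion-matrix metrics.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    jsonlite,
    parallel,
    stats,
    tools,
    utils,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
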