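Package: hetnuc
Title: Heterochromatin Nucleation and Spreading Analysis for Embryonic ChIP-Seq
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for mapping the establishment of H3K9me3 heterochromatin
    across early embryonic stages from low-input chromatin profiling data.
    Implements spike-in quantile-bin normalization of ChIP enrichment tracks,
    a developmental peak taxonomy (phantom filtering, persistent/temporary and
    old/new classification), projection of enrichment onto transposable-element
    consensus coordinates, LTR retrotransposon truncation contrasts, piRNA
    window association and copy-number-scaled TE expression, together with a
    synthetic-genome simulator with known ground truth for end-to-end testing.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite,
    IRanges,
    GenomicRanges,
    rtracklayer
Suggests:
    testthat (>= 3.0.0),
    Rsamtools,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
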