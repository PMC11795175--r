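Package: sigoverlap
Title: Rank-Based Gene-Signature Overlap Statistics and Signed Similarity Indices
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies how strongly differential-expression signatures from
    disease-model transcriptome datasets overlap reference gene-expression
    signatures (hippocampal maturity, brain pH, neural hyperexcitation).
    Implements a running rank-based Fisher/hypergeometric overlap scan with
    four directional sub-tests and a dominant-direction call, signed -log10
    similarity indices, cross-dataset index correlations, and hypergeometric
    pathway-enrichment meta-analysis over gene-set (GMT) collections. A
    synthetic-data module generates expression matrices and reference
    signatures with planted concordant/discordant overlap structure and full
    truth bookkeeping, so every stage of the pipeline is testable end to end
    without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
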