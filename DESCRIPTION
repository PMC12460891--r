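Package: omnifiber
Title: Integrated Proteome-Transcriptome Analysis of Developing Skeletal Muscle
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tested pipeline for integrated label-free proteomics (LFQ) and
    bulk RNA-seq (TPM) analysis of a two-region, six-stage skeletal-muscle
    developmental design. Provides differential abundance/expression calling
    under named threshold policies, presence/absence proteome dynamics between
    adjacent stages, fuzzy c-means trend clustering of temporal profiles with
    cross-region composition analysis, six-type RNA-protein fold-change
    concordance classification, hypergeometric over-representation testing of
    feature sets against domain/term annotations, location-scale batch
    harmonization of cross-dataset ortholog expression, and a synthetic-data
    generator with machine-readable planted truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    mclust,
    e1071,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
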