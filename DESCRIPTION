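Package: secretomap
Title: Placental Secretome Mapping and Biomarker Analysis Pipeline
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Builds a placental secretome map from label-free mass
    spectrometry detection tables and evaluates candidate circulating
    biomarkers. Implements k-of-n sample detection filtering, protein to
    gene identifier mapping, multi-source mouse-human ortholog consensus
    with one-to-many exclusion, combined signal-peptide and Gene Ontology
    secretion classification, cross-species map integration with tissue
    enrichment and pregnancy-complication overlays, internal-standard
    normalization and Spearman average-linkage clustering of plasma
    quantitation, multiple-of-the-median (MoM) biomarker ratio statistics,
    and promoter motif scanning with transcription-factor network
    filtering. A synthetic-data module generates every pipeline input with
    a retained ground truth so each stage can be validated end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    Biostrings,
    ape,
    car,
    igraph
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
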