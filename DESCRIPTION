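Package: histonto
Title: Ontology-Guided Block Classification of Cardiovascular Histology Images
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Block-based classification of 10x cardiovascular histology images
    and ontology-driven correction of the resulting label maps. Images are tiled
    into 100x100 pixel blocks, each block is described by a 292-value local
    binary pattern (LBP) and rotation-invariant LBP (LBPri) texture descriptor,
    and a two-stage cascade support vector machine assigns one of six tissue
    classes per block. A closed-world knowledge base of cardiovascular
    histology facts is then queried to reclassify anatomically impossible organ
    labels to loose connective tissue and to recognise the flat simple
    epithelium lining large light regions bordered by muscle. Includes a
    deterministic synthetic-fixture generator (separable per-class textures,
    organ-like layouts, controllable label corruption), per-class evaluation
    metrics, hit/miss overlays, and a command-line pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    e1071,
    jsonlite,
    png,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
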