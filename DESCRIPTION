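Package: raphemap
Title: Spatial Mapping of Transcriptomic Neuron Subtypes onto Binned ISH Atlases
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Infers the spatial distribution of transcriptomically defined
    neuron subtypes by correlating cluster-averaged single-cell expression
    profiles with spatially binned in situ hybridization (ISH) signal on a
    voxel grid, builds probability-density maps of labeled cell populations,
    and quantifies FISH puncta co-expression. Includes a synthetic-data
    module that plants ground-truth subtype domains, renders ISH-like
    images, and emits labeled-cell and puncta tables so that every stage of
    the pipeline can be validated against a known answer.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    tiff,
    yaml,
    jsonlite,
    withr,
    EBImage
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
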