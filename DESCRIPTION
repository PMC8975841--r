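Package: mucogel
Title: Quantitative Characterization of Alginate-Mucin Mucus-Mimic Hydrogels
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for characterizing engineered alginate-mucin hydrogels used
    as mucus mimics. Estimates effective diffusion coefficients of fluorescent
    tracers from time-lapse channel images by fitting a one-dimensional
    semi-infinite diffusion (complementary error function) model or a
    finite-difference Fickian forward model; measures sessile-droplet contact
    angles and top-view circularity for aqueous two-phase system (ATPS)
    droplet stability; and provides assay calculators for serial-dilution
    spot-plating CFU counts, Live/Dead viability, oscillatory-rheology loss
    tangent and linear viscoelastic region, and hydrogel recipe volumes. A
    synthetic-data module generates every pipeline input (diffusion image
    stacks, droplet images, colony counts, frequency sweeps) with known
    ground truth for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    tiff,
    jsonlite,
    minpack.lm,
    EBImage,
    optparse
Suggests:
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
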