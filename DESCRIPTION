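Package: estuaryscope
Title: Satellite-In Situ Water-Quality Matchup Pipeline for Estuaries
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds harmonized databases pairing in situ estuarine water-quality
    records with multispectral satellite reflectance. Converts heterogeneous
    source tables (differing column names, units, time zones, depth and QA
    conventions) to a unified observation schema; admits sites into estuary
    boundaries with a shoreline error buffer; pairs observations with scenes in
    a +/-24 h window; masks clouds by probability threshold, cloud shadows by
    solar projection, and sun glint by specular geometry; extracts per-band
    pixel statistics in a 30 m matchup disc and applies pixel-count and
    coefficient-of-variation quality filters. Classifies matched chlorophyll
    into trophic-state classes, finds optical water types by fuzzy c-means
    clustering of band-median spectra with validity-index model selection, and
    relates optical types to water-quality variables by nonparametric
    k-nearest-neighbor discriminant analysis with stepwise variable selection.
    A synthetic-world generator emulates estuary geometry, bio-optical
    reflectance scenes with clouds and shadows, water-occurrence rasters, and
    multi-dialect in situ exports with full planted ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    e1071,
    class,
    mclust,
    tiff,
    optparse
Config/testthat/edition: 3
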