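Package: foramforge
Title: Harmonization of Multi-Source Planktonic Foraminiferal Occurrence Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to convert heterogeneous per-sample microfossil occurrence
    tables from deep-sea drilling and literature sources into a single
    harmonized, age-modelled, paleo-rotated, quality-flagged occurrence
    dataset. Includes taxonomic synonym resolution, conversion of five
    abundance encodings to numeric relative abundances, construction of
    depth-age tie points from biostratigraphic and magnetostratigraphic
    marker events, segmented age-depth models (zonal means, piecewise
    interpolation, linear and penalized-spline trends), paleocoordinate
    reconstruction from GPlates-style finite-rotation files, cross-source
    deduplication, stratigraphic-range trimming, and validation metrics
    (species richness per time bin, range completeness, latitude-time
    coverage). A seeded synthetic-core generator with known ground truth
    makes every pipeline stage testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    mgcv,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    ggplot2,
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
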