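Package: lcvmap
Title: Landscape Conservation Value Mapping from Landform and Land Cover
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Derives landscape conservation value (LCV) maps from a digital
    elevation model and a categorical land-cover grid. Landforms are classified
    with the nine-unit landscape model from upslope contributing area (multiple
    or single flow direction), surface curvature and slope, simplified to five
    classes, and crossed with seven land-cover classes into landscape types.
    Expert Likert ratings are aggregated with importance weights into a
    normalized 1-10 conservation-value matrix, mapped onto the landscape-type
    grid, and summarized with zonal statistics and a focal-standard-deviation
    susceptibility mask that flags cells where high- and low-value landscapes
    adjoin. A synthetic volcanic-island generator (radial cone, secondary
    cones, incised channels, elevation-banded land cover, simulated expert
    panels) makes the whole pipeline runnable and testable without external
    data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    pracma,
    stats,
    tools,
    utils,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
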