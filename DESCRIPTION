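Package: breastsym
Title: Landmark-Based Breast Symmetry Index from Frontal Photograph Annotations
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Computes a weighted geometric Breast Symmetry Index (BSI) from
    landmark annotations of frontal torso photographs: jugulum, nipple centres
    and manually traced breast borders in pixel coordinates. Six bilateral
    ratio factors (direct, horizontal and vertical nipple position relative to
    the jugulum, a 24-cut radial nipple-to-border profile, breast area and
    circumference) are combined with questionnaire-derived importance weights
    into a 0-15 score (0 = perfect symmetry) with a mapping onto the four-level
    Harris cosmesis scale. Includes two-way absolute-agreement intraclass
    correlation coefficients for inter-rater reliability, a parametric
    synthetic shape generator with controllable asymmetry and simulated
    annotator jitter, a JSON annotation file format, batch CSV scoring and a
    command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    yaml,
    stats,
    graphics,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
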