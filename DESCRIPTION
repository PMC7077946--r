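Package: smilecurves
Title: Parametric Smile-Aesthetics Template, Landmark Metrics and Overlay Rendering
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Constructs the ideal anterior-tooth template used in aesthetic
    smile analysis from a single central-incisor width, encoding the dominance
    rule, the regressive diagonal-of-a-square width proportion, gingival-zenith
    offsets, the soup-plate incisal outline and the 50-40-30 rule of connector
    spaces. Computes the six horizontal smile lines (upper lip, cervical,
    papillary, contact-point, incisal, lower lip), apparent tooth proportions,
    connector ratios, smile-arc and lip-line classifications and a bilateral
    symmetry score from 2D landmark annotations of frontal smile photographs,
    scoring each quantity against its template ideal. Registers the template
    onto a photograph with a two-point similarity transform and renders
    semi-transparent SVG or PNG overlays. Includes a synthetic-fixture
    generator of ideal and deformed landmark sets for fully self-contained
    testing, and a command-line interface.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    png,
    stats,
    tiff,
    tools,
    utils
Suggests:
    EBImage,
    withr,
    optparse,
    testthat (>= 3.0.0),
    xml2,
    yaml
Config/testthat/edition: 3
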