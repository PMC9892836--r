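Package: itmap
Title: Mapping In-Transit Melanoma Metastases onto Lymphatic Drainage
    Sectors of the Lower Extremity
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to map primary melanomas and in-transit metastases (ITM)
    of the lower extremity onto anatomically defined lymphatic drainage
    sectors of a canonical leg surface.  Provides a parametric triangle-mesh
    leg model with named bone landmarks and four drainage sectors
    (posterolateral, posteromedial, anterolateral, anteromedial including
    the toes), landmark-based rigid registration of patient coordinates
    with mirroring of right-sided cases, skin-surface geodesic distances
    between lesions, per-patient drainage concordance scoring (full,
    partial, no match), cohort-level risk-factor statistics (chi-square,
    Mann-Whitney U, logistic regression with odds ratios), and a synthetic
    cohort-and-lesion generator for end-to-end validation of the pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    igraph,
    jsonlite,
    stats,
    utils,
    grDevices,
    graphics,
    tools
Suggests:
    testthat (>= 3.0.0),
    mgcv,
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
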