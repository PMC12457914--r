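Package: hullscape
Title: Topological Colour Landscapes of Pistachio Hull Maturation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Image-based assessment of pistachio nut maturity and blank-kernel
    incidence from hull surface colour. Segments plate photographs into
    per-nut pixel ensembles, locates each nut's tip by principal-axis
    analysis, builds a hierarchical-clustering reference palette of major
    hull colours, derives tip-anchored colour-proportion features, screens
    feature categories against kernel status with contingency-table
    ensemble testing (categorical exploratory data analysis), assembles
    binary colour landscapes with Ward-D2 dendrograms and k-nearest-
    neighbour profiles, and assigns growth stages and blank-prevalence
    estimates with a neighbourhood-vote algorithm. Includes a synthetic
    plate and feature-table generator with known ground truth, and
    growing-degree-day accumulation for anchoring developmental time
    points.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    EBImage,
    tibble,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    stats,
    utils,
    png,
    ape,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
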