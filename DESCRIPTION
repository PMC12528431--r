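Package: seasonccm
Title: Seasonal Trophic Interaction Inference from Survey Time Series
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Infers season-specific trophic controls (bottom-up and top-down)
    from multi-decadal plankton and fish survey records. Builds seasonal
    interannual abundance series (ln(x+1) transform, season-window averaging,
    LOESS gap filling, z-normalization), detects directional dynamic coupling
    with convergent cross mapping (time-delay embedding, simplex projection,
    library-size convergence) tested against a seasonal-surrogate null, and
    ranks candidate predators by cross-validated boosted-regression-tree
    relative influence with partial dependence curves. Includes seasonally
    forced predator-prey simulators with known coupling structure for
    validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils,
    xgboost
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
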