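Package: veinr
Title: Quantifying the Arrangement of Lateral Veins Along Leaf Midveins
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing the spacing of lateral (secondary) veins
    along the midvein of dicot leaves from digitized vein-origin
    coordinates. For every lateral vein the spacing ratio r =
    d_opposite/d_same is computed, pooled per species, and scored for
    departure from unimodality with Hartigan's dip test (Monte-Carlo
    p-values; dip statistic in C). Species groups (alternate vs. opposite
    phyllotaxis, woody vs. herbaceous) are compared with the Brunner-Munzel
    rank test. A synthetic arrangement generator spans the continuum from
    ideal opposite to ideal alternate vein placement, with internode
    variability, positional jitter and irregular same-side insertions, and
    mirrors the compound-leaf (ternate) design used to test whether
    irregular (r > 1) cases appear as mirror images on left/right leaflet
    pairs.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    tibble,
    utils
LinkingTo: Rcpp
Suggests:
    dplyr,
    ggplot2,
    quadprog,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
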