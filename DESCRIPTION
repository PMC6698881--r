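Package: twinwb
Title: Within- and Between-Family Polygenic Score Decomposition for Twin Cohorts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools to separate within-family from between-family polygenic
    score prediction in dizygotic (DZ) twin cohorts. Implements the
    random-intercept decomposition model with group-mean centering of the
    score predictor, the intraclass correlation and the ICC-weighted total
    effect, twin-pair cluster bootstrap percentile intervals and coefficient
    difference tests, attenuation statistics and socio-economic-status
    conditioning contrasts, quantile analysis of absolute within-pair score
    differences with regression through the origin, Benjamini-Hochberg false
    discovery rate control, and a genetic-relationship-matrix sensitivity
    model. A forward simulator of DZ twin families (Mendelian transmission,
    parental genetic nurture, assortative mating, population stratification)
    provides ground truth for every estimator.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    lme4,
    vcfR
Config/testthat/edition: 3
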