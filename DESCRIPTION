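Package: uavheight
Title: UAV Plant-Height Phenotyping and Quantitative Genetics for Field Trials
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Extracts plot-level plant height from UAV photogrammetric
    elevation rasters: a digital terrain model is interpolated from
    bare-ground control polygons (TIN), the plant height model is the
    per-pixel difference between surface and terrain, and plot heights come
    from an upper-canopy-boundary sampling rule with rejection of values
    that cannot be spike height. Downstream tools validate the heights
    against ground truth (regression, RMSE, bias), estimate variance
    components and broad-sense heritability for balanced multi-environment
    trials, map QTL in doubled-haploid populations by inclusive composite
    interval mapping in regression form, and run ridge-regression BLUP
    genomic prediction with cross-validation and marker-exclusion
    experiments. A synthetic wheat-field generator (linkage map, DH
    genotypes, plot phenotypes, rendered elevation rasters with known
    ground truth) makes the whole pipeline testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    graphics,
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
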