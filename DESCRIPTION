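Package: receptarch
Title: Quantitative Receptor Autoradiography and Laminar Receptor
    Fingerprint Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Analysis pipeline for quantitative in vitro receptor
    autoradiography of the cerebral cortex. Fits film calibration curves
    from co-exposed radioactivity standards, converts gray values to
    binding-site densities (fmol/mg protein), extracts laminar density
    profiles along pial-to-white-matter traverses, partitions them into
    supragranular, granular and infragranular strata, builds
    multi-receptor fingerprints per area and stratum, and runs the
    multivariate (Ward clustering, k-means cluster-number selection,
    non-metric multidimensional scaling, regularized discriminant tests)
    and univariate (per-receptor ANOVA with Bonferroni correction,
    gatekept one-sample t-tests) statistics used to segregate cortical
    areas and layers. Includes a synthetic-phantom generator that renders
    ground-truth density tables into autoradiograph images so the whole
    pipeline is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    MASS,
    cluster,
    minpack.lm,
    jsonlite,
    yaml,
    ape,
    tiff,
    png,
    stats,
    tools,
    utils,
    graphics,
    grDevices
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
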