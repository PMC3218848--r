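Package: lefse
Title: Linear Discriminant Analysis Effect Size for Metagenomic Biomarker
    Discovery
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Identifies features (taxa, pathways, gene families) that
    differentiate two or more biological classes in metagenomic
    feature-abundance tables.  Couples a Kruskal-Wallis class-level screen
    with a subclass-level Wilcoxon biological-consistency gate and ranks
    the surviving features by a bootstrapped linear discriminant analysis
    effect size on a base-10 logarithmic scale.  Includes LDA-score
    barplots, taxonomic cladograms drawn from clade-path feature
    identifiers, per-feature abundance histograms, and a synthetic
    Gaussian benchmark measuring type I and type II error of the
    detectors.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    MASS,
    ggplot2,
    rlang,
    stats,
    utils,
    grDevices,
    graphics
Suggests:
    testthat (>= 3.0.0),
    ape,
    jsonlite,
    optparse,
    withr
Config/testthat/edition: 3
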