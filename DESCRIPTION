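Package: beesignal
Title: Bee-Vision Colour Modelling and Reward-Signal Analysis for Floral Displays
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Models floral reflectance spectra into the hexagon colour space of
    trichromatic bee vision (quantum catches with von Kries adaptation, chromatic
    and achromatic contrasts, spectral purity against the monochromatic locus),
    discretizes flower-module colours into UV/hue categories by band-wise
    reflectance thresholds, reduces colour and size traits through a nested
    principal-component hierarchy, and tests reward-signal associations with
    permutation and phylogenetic comparative methods: PERMANOVA and PERMDISP,
    Monte-Carlo chi-square with standardized residuals, Blomberg's K,
    simulation-based phylogenetic ANOVA, ordinary least-squares integration
    models, and linear mixed models for intrafloral modularity. A synthetic
    community generator with known ground truth supports end-to-end validation
    of every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    ape,
    vegan,
    lme4,
    lmerTest,
    emmeans,
    lmtest,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    phytools
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
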