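Package: ecostab
Title: Ecological Stability Assessment of Mine-Dump Restoration Chronosequences
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantitative assessment of ecological restoration on reclaimed
    open-pit mine refuse dumps. Computes plant community diversity indices
    (Shannon-Wiener, Simpson, Pielou, Margalef), reproduces significance-letter
    group comparisons (one-way ANOVA with Tukey HSD and a compact letter
    display), performs redundancy analysis of plant community characteristics
    on soil properties with a Monte Carlo permutation test and
    restoration-to-reference ordination distances, derives an entropy-weighted
    coupling-coordination ecological-stability index with a five-band
    classification of stability and vegetation/soil development, and fits a
    logistic succession model of stability against restoration age. A
    synthetic chronosequence generator with known latent recovery trajectories
    makes the whole pipeline testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    minpack.lm,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    vegan,
    withr,
    yaml
Config/testthat/edition: 3
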