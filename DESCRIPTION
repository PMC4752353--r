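Package: pelletdiet
Title: Quantitative Diet Analysis from Faecal Pellets
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for quantitative trophic ecology from faecal-pellet prey
    counts: diet composition by numeric frequency, presence, volume and dry
    biomass (with geometric prey-volume models and length-mass allometry);
    Ivlev-Jacobs and Vanderploeg-Scavia electivity against availability
    samples; Hill-number true-diversity profiles with Simpson variance and
    bootstrap Tukey-like pairwise contrasts; permutational multivariate
    analysis of variance and multivariate dispersion homogeneity on
    ecological distance matrices; G-tests, Fisher exact and Kruskal-Wallis
    frequency tests; and an overdispersed (Dirichlet-multinomial) synthetic
    data generator with known ground truth for calibration and power
    studies.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    vegan,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    readxl,
    optparse,
    withr
Config/testthat/edition: 3
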