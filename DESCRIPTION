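Package: ssdscreen
Title: Phylogenetic Screening of Gene Family Size Against Sexual Size
    Dimorphism
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: A comparative-genomics pipeline linking mammalian sexual size
    dimorphism (SSD) to gene-family size evolution. Derives SSD, log body
    mass and relative brain size from raw masses and tests Rensch's rule by
    major-axis regression; filters gene-family count matrices by prevalence,
    maximum count and variance; screens each family with a two-predictor
    phylogenetic generalized least squares fit under Brownian motion,
    converting t statistics to correlation-scale effect sizes and
    classifying families as expanding or contracting after
    Benjamini-Hochberg correction; tests GO-term enrichment of focal family
    sets against equally sized random draws with Z-score nulls; and
    computes brain expression-rank bootstrap statistics, temporal
    trajectory slopes and sex-biased fold-change tests. A synthetic-data
    module generates phylogenies, traits, family counts, GO annotations and
    expression tables with known ground truth so every stage is testable
    without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    ape,
    stats,
    utils,
    withr,
    yaml
Suggests:
    jsonlite,
    nlme,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
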