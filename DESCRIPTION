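Package: geneaction
Title: Inheritance of Transcript Abundance in F1 Hybrids
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Estimates the mode of gene action of transcript abundance in F1
    hybrids from parent and hybrid RNA-seq counts. Implements a negative
    binomial Wald test for differential abundance between the two parents,
    computes the additive effect, dominance effect and degree of dominance
    (k = d/a) per transcript, classifies gene action (additive, partially
    dominant, dominant-recessive, transgressive), compares k distributions
    across categories of genetic crosses (Kolmogorov-Smirnov and Fisher
    tests), relates gene action and expression divergence to gene regulatory
    network connectivity, and quantifies the propagation of gene action from
    trans-acting regulators to their targets. Includes a synthetic-data
    generator with known ground truth for counts, networks and propagation
    rules, and a configurable pipeline runner.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    igraph,
    jsonlite,
    Matrix,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    withr,
    yaml
Suggests:
    DESeq2,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
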