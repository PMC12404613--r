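Package: epineutral
Title: Neutrality Functions for Double-Mutant Fitness and Mechanistic
    Growth Models
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for genetic-interaction analysis of double-mutant
    fitness data. Implements the Product, Additive, Minimum and
    feedback-derived (Scott-Hwa) neutrality functions, residual
    (epistasis) statistics with binned median/quartile summaries,
    readers and preprocessing filters for SGA-style double-mutant
    fitness tables, Gene Ontology biological-process pair analysis,
    a synthetic-data generator with known ground truth, and two
    mechanistic models of cell growth: the two-sector proteome
    allocation model with growth-optimizing feedback (including the
    closed-form double-mutant fitness and its no-feedback Minimum
    limit) and a coarse-grained whole-cell ODE model of nutrient
    import, metabolism, transcription, ribosome-mRNA competition and
    translation, with in-silico pairwise mutational scans and a sweep
    of the transcription saturation parameter.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    deSolve,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
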