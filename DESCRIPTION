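Package: acidFBA
Title: Amino-Acid-Resolved Enzyme-Constrained Flux Balance Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Extends enzyme-constrained genome-scale metabolic models
    (GECKO-style ecGEMs) so that the growth-limiting protein pool is routed
    through the twenty proteinogenic amino acids at stoichiometries given by
    each enzyme's sequence. Provides construction of the amino-acid
    composition matrix from protein sequences, rewiring of enzyme draw
    reactions through amino-acid drains, growth maximization and
    parsimonious flux minimization, drain-level flux variability analysis,
    chemostat growth-rate sweeps, random nutrient-condition sampling, and
    quadratic-programming fits of species-specific amino-acid distributions,
    together with a synthetic toy-model generator with analytically known
    optima for testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    xml2,
    Biostrings,
    quadprog,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse,
    knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
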