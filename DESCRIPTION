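Package: sgcevolve
Title: Stochastic Evolution of Genetic Coding Tables
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A passage-based Monte-Carlo simulator for the emergence of
    genetic coding tables: per-passage assignment initiation, decay and
    mutational capture on the 64-codon space, simplified Crick wobble
    (continuous or late), and six capture mechanisms based on amino-acid
    coevolution and polar-requirement paralogy.  Ships the standard genetic
    code, corrected polar requirements and a biosynthetic conversion map as
    plain-text fixtures, and provides three code-order statistics (spacing,
    distance to the standard code, and neighborhood polar-requirement
    difference) with progress-value normalization, plus population
    experiment harnesses for kinetic, steady-state and late-wobble studies.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr,
    jsonlite,
    knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
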