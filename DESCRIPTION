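Package: hzadmix
Title: Admixture, Asymmetry, and Character Displacement Analysis for
    Two-Species Hybrid Zones
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for analysing reinforcement contact zones between two
    hybridizing species genotyped at codominant multi-allelic
    (microsatellite-style) loci. Implements maximum-likelihood hybrid-index
    estimation from parental reference allele frequencies with
    profile-likelihood confidence intervals, F1 and CI-based hybrid
    classification, randomization tests for differences in hybridization
    frequency with sequential Bonferroni correction, exact binomial tests of
    maternal-parent asymmetry, Weir-Cockerham Fst and Slatkin Rst distance
    matrices, principal coordinates analysis, Mantel isolation-by-distance
    tests, a sympatry-residual randomization test, temperature-corrected
    acoustic-signal regressions, and a reproductive-character-displacement
    metric. Includes a seeded synthetic contact-zone generator (GENEPOP and
    STRUCTURE two-row I/O) so the whole pipeline is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    geosphere,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    vegan,
    ape
Config/testthat/edition: 3
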