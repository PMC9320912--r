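Package: coldscore
Title: Multi-Trait Fuzzy-Membership Evaluation of Cold Resistance in Plant Genotype Panels
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for screening plant germplasm panels for cold resistance
    from two-temperature (control vs. chilling) phenotype trials. Implements
    the cold-resistance coefficient (stress/control trait ratio), the
    direction-aware fuzzy membership-function transform, the comprehensive
    per-genotype resistance score, per-trait rate change and genetic
    coefficients of variation, balanced two-way factorial ANOVA
    (genotype x temperature), Pearson correlation screening, eigenvalue-
    thresholded principal component analysis, and Ward hierarchical
    classification of genotypes into ordered resistance types. Includes
    derived-trait helpers (root-shoot ratio, membrane stability index,
    water-use efficiency, a Rubisco carboxylation proxy, 2^-ddCt relative
    expression) and a calibrated synthetic cohort generator for validating
    the full pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    tools,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    ape
Config/testthat/edition: 3
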