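Package: pgsbias
Title: Structural Models of Bias in Polygenic Score Studies
Version: 1.0.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Tools for interpreting associations between polygenic scores,
    environmental exposures, and phenotypes through standardized linear
    structural (path) models. Provides exact model-implied correlation
    matrices for acyclic path diagrams; closed-form bias expressions for
    measurement-error attenuation, residual genetic confounding after
    adjusting for an unreliable polygenic score, mediation inflation, and
    collider-driven bias amplification; Gaussian structural simulators and
    selection machinery that reproduce each bias by Monte Carlo; a
    heritability-informed sensitivity analysis that recovers the
    genetically de-confounded exposure effect from summary correlations;
    and a genotype-level trio simulator for Mendelian transmission,
    non-transmitted allele scores, genetic nurture, assortative mating,
    and population stratification.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
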