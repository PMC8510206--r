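Package: pepscreen
Title: Virtual Screening of Anticancer Peptides from In Silico Protease Digests
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An end-to-end pipeline for biomimetic anticancer-peptide (ACP)
    discovery from a proteome: in silico protease digestion with configurable
    cleavage rules (pepsin by default), physicochemical profiling (net charge,
    GRAVY hydropathy, Eisenberg hydrophobic moment, residue composition),
    consensus screening over external machine-learning predictor score tables
    with mode-of-action stratification, greedy single-substitution peptide
    redesign, and MTT dose-response analysis with four-parameter logistic IC50
    fitting, one-way ANOVA with Dunnett many-to-one comparisons, and
    combination-treatment grids. Includes seeded synthetic-data generators for
    proteomes, predictor score tables with known labels, and MTT plates, so
    every stage is testable without external services.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Biostrings,
    minpack.lm,
    multcomp,
    jsonlite,
    yaml,
    stats,
    utils,
    graphics
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
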