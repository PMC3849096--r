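Package: cofactorscope
Title: Constraint-Based Dissection of Cofactor Metabolism in Genome-Scale
    Metabolic Models
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for dissecting redox-cofactor (NADPH) metabolism in
    genome-scale metabolic networks with constraint-based analysis: flux
    balance analysis (FBA) and flux variability analysis (FVA) on SBML
    models, expression-constrained flux prediction (E-flux) from
    gene-protein-reaction rules, enumeration of alternative optimal flux
    distributions via integer cuts for cofactor-demand estimation, a
    knockout/restore screen that identifies alternative cofactor-producing
    reactions, Biolog phenotype-microarray growth calling, model-versus-
    phenotype consistency scoring, and minimal-addition refinement
    proposals. Includes seeded generators for small synthetic metabolic
    networks with planted cofactor producers, expression profiles and
    96-well plates with known ground truth, so every analysis step is
    testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    xml2,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
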