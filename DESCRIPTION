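Package: gemevidence
Title: Evidence-Annotated Genome-Scale Metabolic Models
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for genome-scale metabolic models that carry their own
    curation record. Stores literature evidence items and phenotype test
    cases inside SBML Level 3 (fbc) model files, validates models by FBA and
    parsimonious FBA simulation of every embedded test case, computes
    structural quality-control statistics (mass balance, dead-end
    metabolites, census tables, evidence-support classes), translates models
    between strains via reciprocal best hits, and contextualizes expression
    data on the model's pathways. Includes deterministic toy-model fixtures
    with analytically known optima so the whole pipeline is testable
    offline, plus a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    xml2,
    jsonlite,
    stats,
    utils
Suggests:
    boot,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
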