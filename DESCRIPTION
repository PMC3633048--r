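Package: ontoeval
Title: Evaluation Framework for Ontology-Based Gene Function Prediction
Version: 0.1.0
Authors@R:
    person("Ontoeval", "Developers", email = "ontoeval@example.org",
           role = c("aut", "cre"))
Description: Tools for assessing computational gene-function predictions
    against Gene Ontology style annotation gold standards. Provides an OBO
    ontology data model with is_a ancestor closure and score up-propagation,
    GAF 2.x annotation and CAFA-style prediction submission readers with
    evidence-code filtering, gene-centric precision/recall and average
    precision, term-centric AUROC with mid-rank tie handling, information
    content and Resnik/Lin semantic similarity, an informativeness criterion
    against a prevalence null, reference baseline predictors (prevalence,
    root-only, annotation carry-forward, per-species incidence), naive rank
    aggregation of predictor ensembles, and a fully seeded synthetic
    benchmark generator (ontology, annotation corpus, waiting-period gold
    standard, simulated predictor families) with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
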