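Package: pkner
Title: Named Entity Recognition Toolkit for Pharmacokinetic Parameter Mentions
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for recognising mentions of pharmacokinetic (PK) parameters
    (clearance, AUC, Cmax, half-life, bioavailability and related quantities) in
    sentences from the scientific literature. Provides a character-offset corpus
    data model with JSON-Lines and CoNLL BIO interchange, a deterministic
    template-based synthetic PK-sentence generator with gold spans, a declarative
    rule-based matcher with context gating and longest-match resolution, a
    trainable BIO sequence tagger (averaged-perceptron backend with a pluggable
    encoder contract carrying a transformer fine-tuning recipe), entity-level
    strict and partial matching evaluation with pairwise-F1 inter-annotator
    agreement, and a model-in-the-loop active-learning simulator with an
    uncertainty-vs-random sampling experiment.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
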