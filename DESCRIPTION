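Package: daphniachip
Title: Behavioral Ecotoxicology Pipeline for Chip-Cultured Daphnia magna
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for chip-based behavioral ecotoxicology with Daphnia magna
    neonates kept in perfused millifluidic chambers. Provides a stochastic
    hop-and-rest locomotion simulator with dose-dependent activity modulation
    and Hill-model immobilization, synthetic video rendering of back-lit
    chambers, blob detection and multi-animal trajectory linking, locomotor
    endpoint extraction with control normalization and response-syndrome
    classification (hypoactivity, hyperactivity, cessation), binomial
    maximum-likelihood Hill dose-response fitting with bootstrap confidence
    intervals, and a tanks-in-series washout model of chamber medium exchange.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    EBImage,
    deSolve,
    jsonlite,
    yaml,
    png,
    Rcpp,
    stats,
    utils,
    tools,
    graphics
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
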