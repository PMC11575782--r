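Package: ablresist
Title: Dynamic Modelling of Drug Resistance in Abl1 Kinase Inhibition
Version: 1.0.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Tools to study how mutations of the Abl1 kinase confer
    resistance to inhibitor treatment in chronic myeloid leukaemia.
    Derives microscopic rate constants (substrate and inhibitor binding,
    conformational switching) from measurable quantities such as kcat, KM,
    IC50 and inhibitor residence times; simulates a four-state enzyme
    kinetics model driven by fluctuating plasma concentrations from a
    multiple-dose one-compartment pharmacokinetic model; and computes
    resistance indicators, including the inhibitory reduction prowess
    (IRP) and the effective IC50 ratio, that rank treatments per mutation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    deSolve,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
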