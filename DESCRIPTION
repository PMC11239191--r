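Package: porefpt
Title: First-Passage-Time Calculations for Charged Polymers in Nanopores
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Constructs the one-dimensional interaction potential experienced by a
    charged biopolymer (polypeptide or nucleic acid) threading a nanopore from its
    residue sequence, electroosmotic-flow parameters, polymer entropy, and
    user-defined auxiliary force terms, and computes splitting probabilities
    (retraction versus translocation) and conditional mean first-passage times of
    the resulting Smoluchowski drift-diffusion process by spatial integration, per
    applied transmembrane voltage. Includes closed-form and Euler-Maruyama
    simulation oracles for validation, JSON configuration persistence,
    tab-separated import and export of profiles and results, and a command-line
    interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    seqinr,
    stats,
    utils,
    graphics,
    grDevices
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
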