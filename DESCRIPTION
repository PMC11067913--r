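Package: cladorange
Title: Ancestral Range Estimation Under Dispersal-Extinction-Cladogenesis Models with Founder-Event Speciation and Fossil Node Constraints
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Likelihood inference of geographic range evolution on dated
    phylogenies over a discrete, size-capped range state space. Implements the
    DEC, DIVALIKE and BAYAREALIKE cladogenetic model families, each with an
    optional founder-event ("jump") weight j, anagenetic dispersal and
    extirpation rates, fossil-based node constraints that force ancestral
    ranges to include particular areas, maximum-likelihood fitting with AICc
    model selection, marginal ancestral range estimation, and summaries of
    dispersal, extirpation and supercontinent-scale range transitions. A
    forward simulator generates dated trees and tip ranges under the same
    processes, with full event logs, so every stage of the inference chain can
    be validated against known histories.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    Matrix,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
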