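Package: selfix
Title: Fixation of Mutant Alleles Under Partial Selfing and Biphasic Selection
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Theory and simulation tools for the fate of a mutant allele in a
    hermaphroditic plant population with a mixed mating system (partial
    self-fertilization) and selection acting in the haploid gametophyte phase,
    the diploid sporophyte phase, or both. Provides the exact one-generation
    life-cycle recursion of genotype frequencies, critical selfing rates beyond
    which a mutant allele fixes deterministically, Wright's flux-equilibrium
    allele-frequency density with its fixation probability and gene-fixation
    rate K, the diffusion (Kimura) fixation probability, genetic loads, an
    exact small-population Markov-chain oracle, and a vectorised Monte Carlo
    forward simulator for verification.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    jsonlite,
    tools,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
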