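Package: qmutate
Title: Mutation Spectrum, Replication-Mode, and Mutation-Rate Analysis for Riboviruses
Version: 1.0.0
Authors@R: person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for analysing spontaneous mutation in riboviruses (RNA
    viruses without DNA replication intermediates) from plaque-screen and
    single-burst data, built around the bacteriophage Q-beta read-through
    reporter system. Provides codon-framed mutation-target utilities
    (nonsense-path target sizing, base composition, upstream sequence
    context), mutation-spectrum classification with template-primer mispair
    inference and replicated G-tests, three independent estimators of the
    mutation rate per genome replication (nonsense-path, hitchhiker, and
    null-class/frequency reversion methods), Luria-Delbruck style
    single-burst fluctuation analysis with Poisson goodness-of-fit and a
    log-log clone-size diagnostic of the intracellular replication mode, a
    stochastic burst simulator covering stamping-machine (linear),
    exponential, and mixed replication modes, and a Galton-Watson model of
    mutant lineage loss during plaque growth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    jsonlite,
    Biostrings
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
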