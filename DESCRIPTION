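Package: mitoburden
Title: Modeling the Accumulation of Somatic mtDNA Mutations with Age
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: A configurable simulator of the somatic mitochondrial DNA
    mutation burden per cell as a function of age. Provides closed-form
    expected burdens under uncertain polymerase-gamma error rates and
    mtDNA copy numbers, replication-round accounting for development,
    relaxed-replication turnover and stem-cell cycling, Monte Carlo
    sampling of the per-cell burden distribution in proliferating and
    non-proliferating cells with tail-probability tables and reversed
    CDF exports, deterministic heteroplasmy projection under a per-round
    proliferative advantage, and an optional neutral binomial
    segregation simulator.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports: methods, stats, utils, tools, jsonlite
Suggests: testthat (>= 3.0.0), optparse, withr
Config/testthat/edition: 3
biocViews: Genetics, Software, StatisticalMethod
RoxygenNote: 7.3.3
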