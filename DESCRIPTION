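Package: purgeload
Title: Inbreeding Load, Genetic Purging and Forward Simulation for
    Long-Term Slow-Inbreeding Experiments
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for analysing the long-term fate of the inbreeding load
    in populations undergoing slow inbreeding. Implements the
    inbreeding-purging (IP) prediction theory (purged inbreeding
    coefficient recursion, fitness and load trajectories, least-squares
    estimation of the purging coefficient), the lethal-equivalents
    estimator of the inbreeding load from paired noninbred/inbred
    productivity assays with bootstrap inference, deterministic
    mutation-selection-balance construction of deleterious-mutation
    genomes under gamma distributions of fitness effects with a lethal
    class, and an individual-based dioecious Wright-Fisher forward
    simulator of the natural population / base population / derived line
    design. A synthetic-data generator emulates the paired full-sib
    productivity assay so that every estimation stage can be exercised
    against known truth.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
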