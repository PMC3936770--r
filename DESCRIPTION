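Package: cpgcollab
Title: Stochastic Simulation of Collaborative CpG Methylation Inheritance
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Simulates the somatic inheritance of CpG-island methylation
    states across cell generations. A CpG island is modelled as a chain of
    CpG dyads in one of three states (unmethylated, hemimethylated, fully
    methylated) subject to stochastic methylation and demethylation
    attempts between DNA replications. The package implements both the
    standard site-independent reaction scheme and collaborative schemes in
    which a mediator CpG stimulates reactions at a target CpG, a
    parameter-space scanner that discovers bistable schemes and refines
    them towards long-horizon stability, a spatially resolved
    island-in-a-sea model with nearest-neighbour methylation and
    distance-decayed demethylation collaboration, and a mean-field
    companion analysis for the standard scheme including the analytic
    state-lifetime bound.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    stats,
    survival,
    utils
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
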