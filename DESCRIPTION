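Package: coopnet
Title: Agent-Based Dynamics of Cooperative-Norm Spreading on Social Networks
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Simulates the spread of a pro-conservation behavioural norm
    through structured social networks. Agents carry a continuous
    cooperativity in [-1, 1] and update it through pairwise persuasion
    events screened by uniform noise and biased by a weak global external
    field. Provides clustered scale-free (Holme-Kim) and periodic-grid
    network generators with normally distributed interaction weights,
    ensemble simulation with reproducible seeding, intervention protocols
    (delayed field switches and pinned high-degree "influencers"),
    and analysis tools for convergence rates at the consensus crossing,
    tipping-point location by stochastic bisection, and exponential-stage
    diagnostics of the approach to consensus.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    igraph,
    jsonlite,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
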