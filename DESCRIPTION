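Package: driftIMS
Title: Monte Carlo Simulation of Reacting Ion Ensembles in Drift-Tube
    Ion Mobility Spectrometry
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Simulates drift-tube ion mobility spectrometry (IMS) of
    chemically reacting ion ensembles at elevated reduced field strengths.
    Per-species transport (drift velocity, effective and longitudinal
    temperatures, longitudinal diffusion) is derived from user-supplied
    reduced-mobility tables via two-temperature theory and the generalized
    Einstein relations.  Clustering, declustering and fragmentation
    reactions are propagated either deterministically through a Markov
    chain of column-stochastic transition matrices or stochastically per
    particle with random-walk diffusion, yielding species-resolved arrival
    time distributions and 2D IMS-MS spectra.  Includes Gaussian peak
    analysis, analytic peak-width budgets with their power-law scaling
    limits, and fixture reaction networks for nonreacting, dynamically
    clustering and fragmenting systems.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    tools,
    Matrix,
    Rcpp,
    yaml,
    jsonlite,
    minpack.lm
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    deSolve,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
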