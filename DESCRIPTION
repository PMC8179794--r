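Package: gckin
Title: Binding and Trafficking Kinetics of Common Gamma-Chain Cytokines
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Deterministic mass-action model of the common gamma-chain (gc)
    cytokine family (IL-2, IL-15, IL-4, IL-7, IL-9, IL-21) coupling
    receptor-ligand binding with endosomal trafficking. Enumerates the
    family's receptor complexes, enforces thermodynamic detailed balance on
    the binding network, integrates stimulation protocols from a no-ligand
    steady state, and predicts cell-type-specific phosphorylated STAT
    response. Includes Bayesian parameter inference by Markov chain Monte
    Carlo with Geweke convergence diagnostics and posterior predictive
    bands, non-negative canonical polyadic and Tucker tensor decomposition
    of response tensors, Hill dose-response summaries, cell-type specificity
    metrics with rate sensitivities, engineered-ligand (mutein) affinity
    overrides, and a synthetic fixture generator plus command-line entry
    points.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
LinkingTo:
    Rcpp
Imports:
    Rcpp,
    deSolve,
    minpack.lm,
    stats,
    utils,
    jsonlite,
    yaml,
    optparse
Suggests:
    testthat (>= 3.0.0),
    coda
Config/testthat/edition: 3
RoxygenNote: 7.3.3
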