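Package: drugcourtr
Title: Bayesian Spatial Poisson Autoregressive Modeling of Drug-Court
    Effects on County Overdose Mortality
Version: 0.1.0
Authors@R: person("drugcourtr", "maintainers", email = "maintainers@example.org",
    role = c("aut", "cre"))
Description: Fits Bayesian Poisson autoregressive models to county-year panels
    of illicit opioid overdose deaths, with intrinsic conditional
    autoregressive (ICAR) spatial random effects on the yearly growth rates,
    a drug-court exposure indicator, and interaction terms quantifying effect
    heterogeneity. Includes bespoke covariate construction (an arrest
    "targeting index" with tertile bins, principal-component poverty and
    healthcare-access indices), posterior-predictive counterfactual scenarios
    with county and statewide change-in-count and change-in-rate summaries,
    a fully synthetic county-system generator, and parameter-recovery
    experiments. Inference is by Hamiltonian Monte Carlo with a conjugate
    Gibbs update for the spatial precision.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    igraph,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
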