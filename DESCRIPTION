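Package: codcycle
Title: Bayesian Life-Cycle State-Space Model for Northeast Arctic Cod
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Age-structured life-cycle population model for Northeast Arctic
    cod spanning eggs, larvae, 0-group, juveniles, adults and spawners, with
    compensatory (Beverton-Holt) density dependence in juvenile survival,
    cannibalism on the 0-group, separable fishing mortality with random-walk
    effort, Baranov catch, and lognormal observation models for survey
    indices and reported landings. Provides a synthetic-data generator with
    realistic survey missingness, Bayesian estimation of parameters and
    latent states via MCMC (JAGS), convergence diagnostics, and downstream
    analyses of density regulation: juvenile survival trajectories, recruits
    per 0-group, interannual variance dampening across life stages,
    year-class ratios, and bootstrap abundance-survival correlations.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    rjags,
    coda,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
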