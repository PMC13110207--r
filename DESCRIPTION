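Package: rbmscore
Title: Enrollment-Centric Risk-Based Monitoring of Multicenter Trials
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Site-level risk scoring for centralized risk-based monitoring
    (RBM) of multicenter clinical trials, focused on the integrity of the
    enrollment process. Computes six enrollment-integrity indicators per
    site (borderline inclusion index, screen-failure rate, window-period
    violations, screening duration, eligibility distribution divergence,
    and screen-failure pattern shift), maps each to posterior draws via
    conjugate Beta updates or the bootstrap, standardizes them on a robust
    median/MAD scale, and aggregates them into a composite Bayesian site
    risk score with credible intervals, exceedance probabilities, posterior
    ranks, and dual-key flagging with Bayesian false-discovery-rate
    control. Includes a one-factor Bayesian hierarchical model linking all
    indicators through a latent site-risk factor, a multicenter-trial
    simulator with known atypical sites, and a Monte-Carlo harness for
    operating characteristics (sensitivity, specificity, FDR, and ranking
    stability).
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    jsonlite,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    rjags
Config/testthat/edition: 3
RoxygenNote: 7.3.3
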