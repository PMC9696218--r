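Package: dnabuckle
Title: DNA Persistence Length from Euler Buckling of End-Constrained Fragments
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Quantitative model of double-stranded DNA persistence length built
    on Euler column buckling of an isolated, end-constrained DNA fragment
    loaded axially by Manning's counterion-condensation electrostatic force
    and a thermal-fluctuation force.  Provides the bidirectional map between
    persistence length and critical buckling length, its decomposition into
    constraint-only and environment-coupled terms, effective length factors
    for elastically restrained columns, nonlinear least-squares fitting of
    (effective length factor, buckling length) to persistence-length-versus-
    salt data, a three-step temperature-transfer procedure, and a discrete
    worm-like-chain sampler with an end-to-end-distance persistence-length
    estimator for conformation ensembles.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    lhs,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
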