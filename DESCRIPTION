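Package: actinform
Title: Stochastic Form-Finding Models of Cross-Linked Actin Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Generates random two-dimensional cross-linked actin filament
    networks on a rectangular domain, brings them to a stable
    self-equilibrated configuration under constant cross-linker pre-stress
    by nonlinear finite-element form-finding (corotational Euler-Bernoulli
    beam elements for filament segments, tension-only cable elements for
    cross-linking proteins), then stretches the equilibrated networks
    uniaxially to measure effective elastic modulus, filament segment
    re-orientation, and the partition of strain energy between axial and
    bending deformation.  Seeded Monte-Carlo ensembles sweep filament
    density, filament length, cross-linker density, domain size, and
    pre-stress.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    Matrix,
    methods,
    stats,
    utils,
    tools,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    jsonlite,
    yaml,
    igraph,
    withr,
    generics
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
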