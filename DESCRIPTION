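Package: nonlocalgrowth
Title: Non-Local Models of Collective Cell Migration on Growing Domains
Version: 1.0.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Simulation of single-species non-local (integro-)partial
    differential equation models of collective cell migration on
    time-dependent one-dimensional spatial domains undergoing spatially
    homogeneous growth.  The moving domain is mapped to a fixed unit
    reference interval, where a finite-volume method-of-lines scheme with
    a circulant, FFT-accelerated discretization of the non-local
    adhesion/repulsion term and an adaptive stiff time integrator solves
    the transformed equation, including the dilution term induced by
    domain growth.  Includes two packaged case studies (cellular
    aggregation; neural-crest invasion under contact inhibition of
    locomotion), Fourier-type linear stability analysis of the
    homogeneous state on fixed domains, and post-processing metrics
    (total cell mass, invading-front tracking with growth discounting,
    cluster counting).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    deSolve,
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    yaml,
    optparse
Config/testthat/edition: 3
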