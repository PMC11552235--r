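Package: sandplume
Title: Diffusion Modeling and Nerve-Response Quantification for Buried-Prey Chemodetection
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Models when chemicals released by a buried source become
    detectable at the sand surface, and quantifies the sensory data used to
    test such predictions. Implements the free-interface and absorbing
    (method-of-images) Green's functions of the diffusion equation, numerical
    integration of the point-source kernel over a buried prolate-ellipsoid
    capsule, surface-layer detectability analysis against a sensory threshold,
    and an independent Brownian random-walk oracle for the quadrature
    solution. Also provides the companion electrophysiology toolchain:
    rectified Gaussian-envelope quantification of extracellular multi-unit
    nerve recordings, response-kinetics classification, blank-referenced
    dose-response threshold estimation, and seeded generators for synthetic
    nerve traces, dose-response series and behavioral trial tables.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    pracma,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
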