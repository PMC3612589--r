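Package: imoflow
Title: Analytic Optic Flow, Segmentation Cues, and Self-Motion Estimation
    with Independently Moving Objects
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analytic models of instantaneous optic flow for linear motion
    toward a plane and curvilinear motion over a ground plane or toward a
    fronto-parallel plane, with a two-layer composition for an independently
    moving object (IMO). Provides five flow-based segmentation cues
    (accretion/deletion, expansion/contraction, acceleration/deceleration,
    local spatial and temporal curvature), contour-integrated cue strengths,
    linear least-squares estimators of heading (focus of expansion) and of
    the radius of a curvilinear path with segmentation-weighted integration,
    exact closed-form bias terms, static-versus-dynamic discontinuity
    parameter sweeps, and replications of three classic heading/path
    psychophysics configurations. Includes a Middlebury '.flo' codec and a
    finite-difference oracle layer for validating every closed form.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    pracma,
    purrr,
    rlang,
    tibble,
    tidyr,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
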