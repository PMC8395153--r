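Package: ternet
Title: Ternary Logical Modeling of Neuroendocrine-Immune Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Discrete ternary (-1/0/+1) logical modeling of regulatory networks
    spanning the hypothalamic-pituitary-adrenal and -gonadal axes, the peripheral
    immune system and the brain, with conditional (blood-brain-barrier gated)
    interactions. Provides asynchronous Monte Carlo simulation of state evolution
    and attractor discovery, alignment of measured condition-versus-control immune
    and endocrine profiles to model-predicted stable states via directional t-tests
    combined with Brown's method for dependent p-values, two-dimensional topology
    comparison by weighted metric multidimensional scaling with affine registration
    and RMSD scoring, cross-species distance scaling, simulation of timed
    multi-intervention treatment courses, and genetic-algorithm optimization of
    treatment schedules that return the system to its healthy attractor. Ships a
    curated male neuroimmune network together with its six-state stable-state
    catalogue, and synthetic cohort generators for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    stats,
    utils,
    tools,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
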