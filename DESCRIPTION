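Package: reconsim
Title: Multi-View Visibility Simulation for Narrow-Baseline Surgical Camera Rings
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates the continuous-space 3D reconstructability of surgical
    site models observed through a common-main-objective microscope modelled
    as a confocal ring of pinhole cameras. Computes, by exact 2.5D polygon
    clipping rather than rasterization, the subset of a triangle mesh visible
    to at least T cameras, sweeps camera counts, normalizes reconstructable
    areas to a dense-ring benchmark, and fits multi-phase exponential
    saturation curves to the area-versus-cameras relationship. Includes a
    parametric generator for deep operative-corridor meshes (circular and
    deformed-elliptical channels with simple anatomy), binary/ASCII STL input
    and output, and a Monte-Carlo ray-casting oracle for verification.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    polyclip,
    minpack.lm,
    Rcpp,
    stats,
    utils,
    grDevices,
    graphics
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    withr,
    pracma
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
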