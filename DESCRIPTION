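Package: chromdist
Title: Coarse-Grained Chromatin Simulation and FISH Distance-Distribution
    Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Builds nucleosome-resolution segment-chain models of chromatin
    from non-overlapping nucleosome position tracks, samples equilibrium 3D
    configurations with replica-exchange Metropolis Monte Carlo under an
    elastic / screened-electrostatic / anisotropic-internucleosomal force
    field, and compares simulated marker-pair distance distributions with
    two-color FISH distance measurements. Includes nucleosome-removal and
    linker-histone-H1 perturbations, constrained quadratic-programming
    mixture deconvolution of distance histograms, sub-voxel localization of
    two-color spots in synthetic 3D image stacks, and seed-deterministic
    synthetic-data generators for every input.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    stats,
    graphics,
    utils,
    tools,
    quadprog,
    minpack.lm,
    jsonlite,
    xml2,
    tiff
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
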