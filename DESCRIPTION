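Package: vascperm
Title: Quantifying Electroporation-Induced Microvascular Permeability from
    Intravital Fluorescence Time Series
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Pipeline for estimating the apparent diffusion coefficient and
    permeability of electroporated microvessel walls from dorsal-window-chamber
    fluorescence microscopy. Includes a synthetic-data generator with known
    ground truth (acquisition schedule, two-compartment dextran
    pharmacokinetics, rendered image stacks), large-vessel masking and trace
    extraction, background subtraction and pre-pulse normalization, a
    closed-form Bateman model of intravascular tracer concentration, a
    finite-volume solver for Fick diffusion on a periodic capillary unit cell
    with a time-ramped wall diffusion coefficient, genetic-algorithm inverse
    estimation of the wall parameters, a tissue-diffusivity sensitivity sweep,
    and reporting of derived permeability coefficients.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    minpack.lm,
    jsonlite,
    EBImage,
    tiff,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    deSolve,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
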