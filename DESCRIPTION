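Package: waterPET
Title: Quantitative Tumour Perfusion from Dynamic 15O-Water PET
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Kinetic analysis of dynamic 15O-water PET for tumour perfusion.
    Implements the one-tissue compartment model with an explicit vascular
    volume term, spectral (non-negative exponential basis) deconvolution
    against an image-derived arterial input function, bounded nonlinear
    least-squares fitting, input/response delay estimation, FDG-based
    volume-of-interest definition with attenuation-image co-registration,
    lean-mass-corrected SUV metabolic response classification, and the
    cohort statistics used in pharmacodynamic imaging studies. Includes a
    synthetic dynamic-PET phantom generator for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    tools,
    minpack.lm,
    jsonlite,
    yaml,
    RNifti
Suggests:
    pracma,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
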