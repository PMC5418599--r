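Package: locprec
Title: Pointwise Localization Precision and Uncertainty-Aware Tracking for
    Single-Molecule Microscopy
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Maximum a posteriori localization of single fluorophores with an
    EMCCD noise model and physically motivated priors, pointwise precision
    estimation by the Laplace approximation and the Cramer-Rao lower bound,
    blur- and noise-corrected diffusion estimators, and a multi-state diffusive
    hidden Markov model with motion blur and heteroscedastic localization
    errors fitted by variational expectation-maximization, including posterior
    refinement of measured positions. A synthetic EMCCD movie generator with
    full ground truth makes every stage testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    pracma,
    stats,
    utils,
    graphics,
    tiff,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
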