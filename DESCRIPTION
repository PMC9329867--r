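Package: carotRaman
Title: Quantitative Resonance Raman Analysis of Carotenoid-Albumin Complexes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for quantifying carotenoids (beta-carotene, lutein,
    zeaxanthin) complexed with serum albumin in aqueous solution from
    532 nm resonance Raman spectra. Implements Savitzky-Golay smoothing,
    extended multiplicative signal correction (EMSC) with water and
    protein interferent spectra and water internal-standard
    normalization, a Beer-Lambert self-absorption correction with
    nonlinear least-squares estimation of effective path factors, PLS1
    concentration calibration with repeated K-fold cross-validation and
    limit-of-detection estimation, principal components analysis for
    differentiating carotenoid species, and constrained nonlinear
    least-squares unmixing of carotenoid admixtures with per-component
    self-absorption. A synthetic-spectrum generator with ground truth
    supports fully reproducible end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    signal,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    yaml,
    pracma,
    mixOmics
Config/testthat/edition: 3
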