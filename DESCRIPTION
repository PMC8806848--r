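Package: ramanomer
Title: Raman Quantification of Sugar Anomers in Aqueous Mixtures
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for quantifying D-mannose and D-glucose in aqueous
    mixtures from Raman spectra. Implements asymmetric penalized
    least-squares baseline correction, Gaussian/Lorentzian multi-peak
    deconvolution of the anomeric fingerprint region, intensity-ratio
    estimation of pyranose anomer fractions, linear area-based
    calibration of sugar content, and conversion of computed vibrational
    mode tables (frequencies, degeneracies, polarizability-derivative
    invariants) into broadened, anomer-weighted Raman backscattering
    cross-section spectra. A synthetic-spectrum generator reproduces the
    statistical structure of the measurements so every stage is testable
    without instrument data.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Matrix,
    minpack.lm,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
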