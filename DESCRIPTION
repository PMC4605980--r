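Package: ficollnmr
Title: NMR Metabolomic Fingerprinting of Ficoll-Separated Plasma
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Processing and statistical analysis of 1D 1H-NMR plasma
    spectra contaminated by Ficoll separation medium: exponential
    apodization and Fourier transform of free induction decays,
    chemical-shift calibration on the glucose anomeric doublet,
    0.02-ppm bucketing with exclusion of the contaminated 3.30-6.00 ppm
    region, total-area normalization, PLS with canonical discriminant
    analysis and multilevel PLS for paired pre/post-anesthesia designs
    under Monte-Carlo cross-validation, and univariate Wilcoxon /
    Benjamini-Hochberg / fold-change screening of metabolite signals.
    Includes a synthetic plasma-cohort generator emulating metabolite
    peaks, macromolecular baseline, Ficoll contamination and
    anesthesia-related drug signals, so every stage is testable without
    spectrometer data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    mixOmics
Config/testthat/edition: 3
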