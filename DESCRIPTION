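Package: pigmentox
Title: Kinetics and Colorimetry of Pigment Degradation and Lipid
    Oxidation in Emulsions
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for quantifying anthocyanin stability and lipid
    oxidation in oil-in-water emulsions. Fits first-order exponential
    decay models with half-lives to pigment time series and logistic
    (sigmoidal) accumulation models to lipid hydroperoxide and volatile
    aldehyde time series, deriving inflection points and
    inflection-tangent induction times. Converts visible absorbance
    spectra to CIELAB colour under illuminant C with the 2-degree
    observer and computes CIEDE2000 colour differences. Includes linear
    external calibration with inverse prediction, unit conversions, a
    seeded synthetic-data generator that emulates replicate storage
    experiments, and one-way ANOVA with Tukey compact-letter reporting.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    minpack.lm,
    jsonlite,
    stats,
    utils,
    graphics,
    grDevices
Suggests:
    testthat (>= 3.0.0),
    farver,
    withr,
    pracma
Config/testthat/edition: 3
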