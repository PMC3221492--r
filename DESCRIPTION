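Package: nirblend
Title: NIR-Chemometric Calibration and Accuracy-Profile Validation for Drug
    Assay in Powder Blends
Version: 0.1.0
Authors@R:
    person("Analytical", "Developer", email = "dev@example.org",
           role = c("aut", "cre"))
Description: Multivariate calibration pipeline for assaying an active
    pharmaceutical ingredient (meloxicam) in powder blends for tableting from
    near-infrared (NIR) diffuse reflectance spectra. Implements the
    formulation and calibration/validation experimental design, a synthetic
    NIR spectrum generator with the statistical structure the analysis
    assumes (linear mixing in absorbance, baseline drift, multiplicative
    scatter, between-series random effects, additive noise), nine spectral
    pre-treatments (moving-average and Savitzky-Golay smoothing, unit-vector
    and min/max normalization, standard normal variate, Norris gap first and
    second derivatives, deresolve), PLS1 (NIPALS) and PCR regression with
    cross-validated latent-factor selection, and ICH-style external
    validation via accuracy profiles: trueness, variance-component precision,
    beta-expectation tolerance intervals, linearity and compliance.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
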