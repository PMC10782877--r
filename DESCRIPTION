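Package: drswir
Title: Use-Error Robust Optical Property Estimation from Diffuse Reflectance Spectra
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for estimating tissue optical properties (the absorption
    coefficient mu_a and the reduced scattering coefficient mu_s') from visible
    diffuse reflectance spectra captured as 8-bit RGB spectral images. Implements
    a wavelength-independent regressor (WIR): a pair of gradient-boosted tree
    ensembles fitted to 35 whole-spectrum summary features that do not reference
    any specific wavelength, making predictions robust to common device
    use-errors such as wavelength miscalibration, intensity fluctuation and
    detector noise. Includes the full image-to-spectrum preprocessing chain,
    a closed-form short source-detector-separation forward reflectance model
    with a hemoglobin-like absorber for generating labelled synthetic datasets,
    a six-error use-error corruption suite with training-set augmentation, a
    spectral-matching inversion baseline, a small dense neural-network baseline,
    and fivefold / leave-one-group-out evaluation protocols.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    xgboost,
    jsonlite,
    yaml,
    png,
    stats,
    utils,
    tools,
    graphics
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
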