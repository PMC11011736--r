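Package: craterspec
Title: Crater-Spectrum Feature Fusion for LIBS Quantification of Cadmium
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantification of cadmium in botanical powders from laser-induced
    breakdown spectroscopy (LIBS). Implements characteristic peak ratio
    correction (CPRC), a spectral ratio normalization that selects
    matrix-related background wavelengths by correlation with reference
    concentrations; crater-morphology compensation via backward stepwise
    multiple linear regression over nine ablation-crater parameters; and
    crater-spectrum feature fusion calibration with univariate curves, MLR,
    PLSR, least-squares SVM and random forest models, with R2/RMSE and
    LOD/LOQ evaluation. Includes a synthetic data generator emulating
    multi-brand matrix-effect structure for end-to-end benchmarking.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    Matrix,
    jsonlite,
    randomForest
Suggests:
    testthat (>= 3.0.0),
    mixOmics,
    cluster,
    yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
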