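Package: kexmeta
Title: Meta-Analytic Prediction Equations for Potassium Excretion in Dairy Cattle
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Tools for developing and evaluating simple mixed-model prediction
    equations for urinary and fecal potassium excretion in dairy cattle from
    study-level treatment means. Provides database assembly and validation,
    interquartile-range outlier screening, a weighted random-intercept linear
    mixed model estimated by restricted maximum likelihood with the variance
    ratio profiled in one dimension, leave-one-study-out cross-validation, and
    a model-adequacy suite built on the decomposition of the mean square
    prediction error into mean bias, slope bias and random error, together
    with RMSPE, RSR and Lin's concordance correlation coefficient. A seeded
    multi-study synthetic data generator reproduces the assumed data structure
    so that every stage of the pipeline is testable.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports: stats, utils, jsonlite
Suggests: testthat (>= 3.0.0), lme4, optparse, withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
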