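Package: lateralpred
Title: Temporal-Prediction Recurrent Networks and V1-Like Lateral Connectivity
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Implements a Dale-constrained recurrent network trained to predict
    future frames of naturalistic movies, together with the in-silico physiology
    used to characterise it: synthetic movie and grating stimulus generation,
    response-weighted-average receptive field estimation with Gabor
    parameterisation, orientation/direction tuning and modulation-ratio
    analysis, thresholded functional-connectivity motifs with trend tests and
    shuffle controls, ablation and representation-clustering experiments,
    prediction-error unit detection, and a linear-nonlinear neural-response
    fitting stage scored by the normalised correlation coefficient.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    grDevices,
    graphics,
    tools,
    minpack.lm,
    glmnet,
    cluster,
    jsonlite,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
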