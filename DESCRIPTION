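Package: fsetongue
Title: Feature Specificity Enhancement and Kernel Extreme Learning
    Machines for Voltammetric Electronic Tongues
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for classifying liquids measured with pulse-voltammetric
    electronic tongues. Implements feature specificity enhancement (FSE), a
    pairwise radial-basis-kernel feature extractor that cancels the
    common-mode excitation signal shared by working electrodes and keeps the
    class-informative specificity component; a kernel-baseline contrast
    method (KBM); extreme learning machine (ELM) and kernel extreme learning
    machine (KELM) classifiers in closed ridge form; a simulator for
    multi-frequency large-amplitude pulse voltammetry (MLAPV) sensor-array
    responses; and cross-validation protocols (leave-one-replicate-out and
    stratified four-fold) with accuracy/STD reporting and parameter
    sensitivity sweeps.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    e1071,
    MASS,
    randomForest,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
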