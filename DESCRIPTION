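Package: cdaneeg
Title: Conditional Domain-Adversarial Networks for Cross-Subject
    Motor-Imagery EEG Decoding
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Cross-subject decoding of motor-imagery
    electroencephalography (EEG) with conditional domain-adversarial
    neural networks.  Provides a densely connected convolutional feature
    extractor for raw multi-channel EEG trials, a label classifier, and a
    domain discriminator conditioned on the multilinear (outer-product)
    join of features and class probabilities, trained adversarially
    through a gradient reversal layer with entropy-based example
    weighting.  Includes ablation variants (unconditional and unweighted
    discriminators), a multi-subject synthetic EEG generator with
    controllable inter-subject domain shift, leave-one-subject-out
    evaluation and hyperparameter-sweep harnesses, and perturbation-based
    band-amplitude correlation maps for model interpretation.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    signal,
    stats,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
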