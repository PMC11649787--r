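Package: ddmcrowd
Title: Crowdsourced Label Aggregation with Drift-Diffusion Annotator Models
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Tools for binary-label crowdsourcing in which each annotator is
    modeled as a drift-diffusion decision maker. Provides closed-form
    sensitivity, specificity and expected decision times for the
    symmetric-boundary drift-diffusion model, an Euler-Maruyama simulator of
    annotator labels and reaction times on synthetic datasets with a
    sinusoidal decision boundary, mean-field variational inference of
    annotator drift and diffusion parameters and of ground-truth label
    probabilities (with reaction-time regularization or rescaling), a
    Gaussian-process classifier trained on the inferred latent values, an
    evaluation suite for parameter-recovery and classification metrics, and a
    command-line interface for simulation, inference and evaluation runs.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    kernlab,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
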