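Package: fieldlift
Title: Neural Conversion of Low-Field to High-Field Simulated 1H-NMR Spectra
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates paired low-field (100 MHz) and high-field (400 MHz)
    one-dimensional 1H-NMR spectra of metabolite mixtures from parametric
    first-order spin multiplet models, applies a full augmentation workflow
    (reference singlet, uniform noise, chemical-shift jitter, baseline offset,
    artifact singlets and triplets, metabolite dropout), and trains neural
    networks that convert low-field spectra to their high-field equivalents.
    Six conversion architectures are provided (dense autoencoder, convolutional
    autoencoder, U-Net, chunked U-Net, temporal convolutional network, and a
    chunked encoder-only transformer) together with a multilayer-perceptron
    metabolite quantifier, an MSE/early-stopping training loop, and an
    evaluation suite comparing direct low-field quantification against
    convert-then-quantify pipelines by mean absolute percent error.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    grDevices,
    graphics,
    jsonlite,
    yaml,
    Rcpp
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr,
    pracma
Config/testthat/edition: 3
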