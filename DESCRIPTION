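Package: retinacoder
Title: Convolutional and Recurrent Encoding Models of Retinal Ganglion Cells
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Simulates a subunit-based retinal circuit, trains convolutional
    (CNN) and convolutional-recurrent (CRNN) encoders on stimulus/firing-rate
    pairs with a Poisson objective, and recovers the learned computational
    elements: spike-triggered-average receptive fields, SVD spatial/temporal
    factors, 2D-Gaussian receptive-field fits, Moran spatial autocorrelation
    and temporal-regularity kernel importance indices, kernel-pruned reduced
    models, and SSIM-based spatial/temporal scene-complexity maps.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    minpack.lm,
    jsonlite,
    yaml
Suggests: testthat (>= 3.0.0), optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
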