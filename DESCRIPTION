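Package: cspd
Title: Contrast-Free Super-Resolution Power Doppler Microvessel Imaging
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Simulation and reconstruction toolkit for contrast-free
    super-resolution power Doppler (CS-PD) ultrasound microvessel imaging.
    Provides a synthetic microvasculature and flow simulator, a linear
    point-spread-function forward model with tissue clutter and electronic
    noise, SVD clutter filtering and power Doppler reconstruction,
    ultrasound localization microscopy (ULM) target generation, a trainable
    convolutional encoder-decoder that translates short spatiotemporal
    ultrafast-Doppler ensembles into super-resolved microvessel images
    (with L1, feature-space and adversarial training objectives), and
    quantitative evaluation metrics (PSNR, SSIM, vessel FWHM, normalized
    intensity profile MSE, and Fourier-domain global resolution).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    jsonlite,
    yaml,
    tiff
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
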