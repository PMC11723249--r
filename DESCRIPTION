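Package: affnet
Title: Dual-Branch Frequency-Domain Fusion Networks for Histopathology Image Classification
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Implements AFFNet, a dual-branch frequency-domain fusion network for
    multi-subtype classification of breast-cancer histopathology images. Provides the
    DCT-based multi-spectral channel attention (MSCA) and the Fourier filtering
    enhancement operator (FFEO), ConvNeXt-style and Swin-style branch blocks gated by
    them, the per-stage adaptive frequency-domain fusion (AFDF) stage, parameter and
    FLOP accounting against the published budgets, dataset manifests for
    BreaKHis/BACH-style layouts with patch extraction and a nucleus-count filter, a
    synthetic H&E-like image generator for download-free testing, and the full
    training and evaluation protocol (Adam, cosine annealing, macro-averaged metrics).
    All network computation runs on a small built-in reverse-mode automatic
    differentiation engine over base-R arrays.
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
    tools,
    png,
    jsonlite,
    EBImage
Suggests:
    testthat (>= 3.0.0),
    tiff,
    pROC,
    optparse
Config/testthat/edition: 3
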