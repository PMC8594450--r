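Package: iqtask
Title: Task-Based Image Quality Assessment of Deep-Learning Super-Resolution
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Simulates clustered lumpy background phantoms with Rayleigh
    (two-point versus line) or microcalcification-cluster signals, degrades
    them to low resolution under Gaussian blur, decimation and mixed
    Poisson-Gaussian noise, optionally super-resolves them with a small
    trainable convolutional network, and quantifies binary signal-detection
    performance with Hotelling-family linear observers (HO, regularized HO,
    Gabor channelized HO) and learned residual-network observers. Provides
    ROC/AUC analysis with DeLong confidence intervals alongside traditional
    image-quality metrics (ensemble MSE, PSNR, SSIM), and experiment drivers
    for signal-length, network-depth and observer-capacity sweeps.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    tools,
    Rcpp,
    EBImage,
    jsonlite,
    yaml,
    png
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    pROC,
    optparse
Config/testthat/edition: 3
biocViews: Software, StatisticalMethod, Classification
RoxygenNote: 7.3.3
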