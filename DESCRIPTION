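Package: cyclepw
Title: CycleGAN Transfer of Peripheral Pressure Waveforms to Central
    Pressure-Area Dynamics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Maps peripheral (brachial and radial) arterial blood-pressure
    waveforms to central (abdominal aortic) pressure and luminal-area
    waveforms with a one-dimensional CycleGAN: two stacked-GRU generators
    and two convolutional discriminators trained with least-squares (LSGAN)
    or Wasserstein gradient-penalty (WGAN-GP) adversarial losses plus a
    cycle-consistency term. From the reconstructed central pair the package
    rebuilds the pressure-strain hysteresis loop and estimates the
    pressure-strain elastic modulus as an ordinary least-squares slope,
    reporting per-pulse RMSE, mean error, mean absolute percentage error
    and Bland-Altman agreement. Includes a synthetic virtual-subject
    generator with a viscoelastic (Voigt) wall model providing known
    ground-truth stiffness, the four-step preprocessing chain (unit
    conversion, pulse tiling to a fixed window, min-max normalization,
    polyphase resampling) with exact inversion, and a command-line
    interface for reproducible experiments.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    data.table,
    jsonlite,
    Rcpp,
    stats,
    tools,
    utils,
    yaml
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
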