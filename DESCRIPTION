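Package: qcmvisc
Title: Viscoelastic Film Analysis for QCM-D Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Forward modelling and inversion of quartz crystal microbalance
    with dissipation monitoring (QCM-D) data for planar viscoelastic films.
    Implements the exact complex acoustic-load equation for layered media on a
    thickness-shear resonator, power-law viscoelastic dispersion in four
    equivalent representations, the Sauerbrey and Kanazawa-Gordon limits, the
    thin-film graphical recipes for films in air and stiff films in liquid,
    the viscosity-increment (double-layer) interpretation, a full five-parameter
    chi-square fit with profile-likelihood (chi-square landscape)
    identifiability analysis, and a synthetic-experiment generator with
    per-crystal constant offsets plus statistical noise.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    minpack.lm,
    jsonlite,
    yaml,
    withr,
    stats,
    utils,
    graphics,
    grDevices
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
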