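Package: schicsr
Title: Blind Super-Resolution Enhancement and 3D Reconstruction of
    Single-Cell Hi-C Contact Maps
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for enhancing sparse, noisy single-cell Hi-C contact
    matrices by blind super-resolution with a learnable degradation
    kernel and an unrolled alternating estimator/restorer network, and
    for reconstructing 3D chromosome structures from contact maps by
    maximum-likelihood gradient ascent with automatic estimation of the
    contact-to-distance conversion exponent. Includes a synthetic-data
    generator (polymer-like chains, distance-decay contact maps,
    binomial read thinning), an evaluation suite (PSNR, SSIM,
    GenomeDISCO-style reproducibility, Pearson correlation, Kabsch
    superposition, TM-score, insulation-score consistency), and a
    command-line pipeline for simulate, train, enhance, reconstruct and
    evaluate runs with seeded reproducibility.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    bio3d,
    withr
Config/testthat/edition: 3
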