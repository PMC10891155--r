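Package: registain
Title: Virtual Histological Staining with Jointly Trained Registration
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Trains a virtual-staining generator that transforms two-channel
    autofluorescence images of unlabeled tissue into brightfield hematoxylin
    and eosin (H&E) equivalents. A generator, a discriminator and a
    registration network are optimized jointly so that coarsely aligned
    histochemical ground truth is dynamically warped, via a displacement
    vector field and a differentiable spatial transformer, into pixel-accurate
    training targets. Includes the full loss suite (reverse Huber, total
    variation, adversarial, windowed normalized cross-correlation), two-step
    rigid/affine slide registration and tiling, PSNR/SSIM screening of
    training pairs, stain unmixing by color deconvolution, nuclei segmentation
    and quantification, field-of-view staining-artifact screening, and a
    synthetic phantom-tissue generator providing ground truth for every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    EBImage,
    tiff,
    png,
    yaml,
    jsonlite,
    Rcpp
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    knitr,
    rmarkdown
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
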