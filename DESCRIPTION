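Package: nlm3d
Title: Locally Adaptive Non-Local Means Denoising for 3D Micro-CT Volumes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Parameter-free non-local means (NLM) denoising of 3D grayscale
    volumes such as micro-CT scans of stained tissue. Patch sum-of-squared
    differences are computed with a moving-average-filter acceleration, the
    noise standard deviation is estimated per local sub-block from
    pseudo-residuals, and the NLM smoothing parameter is derived
    automatically from the local noise level, the patch size and the
    volume's gray-scale value range, with a tunable kernel-shape exponent
    for non-Gaussian noise. Includes DICOM series, netCDF and multi-page
    TIFF volume I/O, a seedable synthetic phantom generator with Gaussian,
    Poisson-Gaussian and Rician noise models, grayscale line-profile
    evaluation, PSNR, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports: methods, stats, utils, tools, Rcpp, tiff, ncdf4
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0), jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
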