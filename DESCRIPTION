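Package: aberrsim
Title: Synthetic Optical Aberrations and Restoration Analysis for 3D Fluorescence Microscopy
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Physics-based synthetic aberration engine for 3D fluorescence
    microscopy volumes. Builds Zernike-polynomial wavefronts at the objective
    back focal plane, synthesizes ideal and aberrated point spread functions
    for widefield and light-sheet detection, and degrades near-diffraction-
    limited volumes through a modified optical transfer function with
    SNR-controlled Poisson noise, producing realistic training pairs for
    learned restoration. Includes a 3D phantom generator (dots, lines, rings,
    spheres, shells), Richardson-Lucy deconvolution and preprocessing
    baselines (background subtraction, depth attenuation compensation,
    time-lapse intensity renormalization), volumetric image-quality metrics
    (SSIM, PSNR, RMS contrast, photon SNR, DCT Shannon entropy sharpness),
    a tiled prediction harness with seam-free linear blending, and 3D
    fiber and vessel orientation estimation with directional-variance
    statistics.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    tiff,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
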