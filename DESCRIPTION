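Package: rupp
Title: Ultrafast Structural and Angiography Projections for Fourier-Domain OCT
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Generates en-face structural projections of Fourier-domain optical
    coherence tomography (FD-OCT) volumes directly from the raw spectral
    interferograms, without a Fourier transform, and angiography (OCTA)
    projections by applying speckle-variance or eigen-decomposition clutter
    filtering to stacks of repeated two-dimensional projections. The
    conventional FFT-based reconstruction pipeline (A-line reconstruction,
    depth-summation projection, volumetric speckle variance and frame-wise
    eigen filtering, multi-repeat ground truth) is included as the reference,
    together with PSNR/SSIM/MSE image-quality evaluation and a swept-source
    interferogram simulator with known reflectivity and vessel ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    tiff,
    png,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
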