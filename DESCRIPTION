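Package: aosim
Title: Adaptive-Optics Structured-Illumination Microscopy Simulation and Reconstruction
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Computational core for adaptive-optics three-dimensional
    structured-illumination microscopy (3D-SIM). Provides Zernike wavefront
    machinery and scalar Fourier-optics point-spread/optical-transfer function
    simulation under pupil aberrations; a forward simulator for widefield,
    three-beam structured-illumination, confocal guide-star, and
    Shack-Hartmann acquisitions with seeded shot and read noise; the full
    3D-SIM reconstruction pipeline (phase-stepped order separation,
    overlap-correlation estimation of pattern wave vector, phase and
    modulation weights, and a generalized Wiener filter with notch, Tukey and
    apodization filters); sensorless modal adaptive-optics optimization with a
    spatial-frequency image-quality metric; Shack-Hartmann gradient sensing
    with Fourier-transform wavefront reconstruction, Gram-Schmidt Zernike
    decomposition, and closed-loop deformable-mirror correction; plus
    evaluation metrics (SNR against an adaptive threshold, Gaussian-fit FWHM,
    aberration sweeps of the transfer-function overlap amplitudes).
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    tibble,
    dplyr,
    rlang,
    generics,
    ggplot2,
    tiff,
    yaml,
    minpack.lm
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
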