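Package: ogmua
Title: Oscillating-Gradient and Microscopic-Anisotropy Diffusion MRI:
    Simulation, Fitting and Test-Retest Statistics
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for oscillating gradient spin echo (OGSE) and
    microscopic anisotropy (muA) diffusion MRI analysis: construction of
    diffusion-encoding gradient waveforms (PGSE, cosine OGSE, frequency
    tuned bipolar, linear and spherical tensor encoding) with numeric
    b-tensor and gradient-modulation power-spectrum computation; synthesis
    of mouse-brain-like multi-compartment phantoms and test-retest cohorts
    with Rician noise; per-frequency mean-diffusivity mapping and
    power-law dispersion-rate fitting; joint non-negative kurtosis fitting
    of powder-averaged linear and spherical encodings for muA and muFA;
    and reproducibility analytics (Bland-Altman, between- and
    within-subject coefficients of variation, sample-size estimation, SNR
    maps).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    RNifti,
    jsonlite,
    stats,
    utils
Suggests: testthat (>= 3.0.0), withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
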