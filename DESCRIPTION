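Package: prfmap
Title: Population Receptive Field Mapping and Eccentricity-Band Analysis of Visual Field Maps
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for population receptive field (pRF) mapping of human visual
    cortex from BOLD time series: generation of the moving-bar aperture stimulus
    used in retinotopic mapping experiments, a 2D isotropic Gaussian pRF forward
    model with hemodynamic response convolution, grid-plus-refinement model
    fitting with variance explained as the goodness-of-fit measure,
    eccentricity-band statistics of visual field maps (surface-area percent
    distribution, variance explained, pRF size across 1-degree bands), and
    two-group multivariate comparisons (Wilks' lambda MANOVA, one-way ANOVA,
    pooled t-tests). Includes a synthetic cortical sheet generator with known
    retinotopic ground truth emulating young, healthy-aging, and
    Alzheimer's-like scenarios, so every pipeline stage can be validated against
    simulated data with known parameters.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports: stats, graphics, grDevices, utils
Suggests: testthat (>= 3.0.0), jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
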