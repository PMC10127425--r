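Package: chromaFish
Title: Quantification of Dynamic Body Coloration in Fish from Photographs
        and Reflectance Spectra
Version: 0.9.0
Authors@R: person("Package", "Author", email = "author@example.org",
        role = c("aut", "cre"))
Description: Tools for quantifying dynamic body coloration of fish from
        standardized digital photographs and reflectance spectrometry, and for
        relating coloration to dominance behaviour in dyadic contests.
        Implements white-standard image calibration, CIELab belly sampling and
        Lab-chromaticity, HSB-threshold segmentation of colored areas with a
        minimum-component rule, relative colored area and a Fulton-type body
        condition index; a trichromatic photoreceptor quantum-catch visual
        model with Govardovskii pigment templates, Maxwell-triangle
        chromaticity and achieved chroma; variance-component repeatability
        with parametric-bootstrap confidence intervals and boundary-corrected
        likelihood-ratio tests; binomial and Gaussian mixed-model analyses of
        dominance and display with stepwise likelihood-ratio reduction; and a
        synthetic-data generator producing images, spectra, repeated measures
        and dyadic-contest datasets with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports: methods, stats, grDevices, utils, lme4, MASS, nortest,
        jsonlite, png
Suggests: testthat (>= 3.0.0), tiff, optparse, withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
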