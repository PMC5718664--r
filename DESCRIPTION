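Package: catphanqa
Title: CATPHAN Image-Quality Analysis for Cone-Beam CT
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Automated image-quality analysis of CATPHAN-504 phantom scans
    from linac-mounted cone-beam CT systems (Elekta XVI, Varian OBI), for
    routine image-guided radiotherapy quality assurance.  Reads axial DICOM
    CT series, applies the stored-pixel rescale to Hounsfield units, and
    measures pixel-value stability versus tube output (mAs), noise,
    contrast-to-noise ratio on the CTP404 sensitometry module, the
    uniformity index (cupping/capping) on the CTP486 module, high-contrast
    resolution on the CTP528 line-pair module, and low-contrast
    detectability on the CTP515 module.  Includes a synthetic CATPHAN scan
    generator with parametric noise, uniformity-artifact, pixel-drift and
    blur models so every estimator can be validated against known ground
    truth, plus the built-in XVI and OBI clinical protocol presets and
    their total-mAs arithmetic.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    EBImage,
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
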