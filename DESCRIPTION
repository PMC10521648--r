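Package: uvstain
Title: Label-Free Virtual Immunohistochemistry from Multispectral Deep-UV Microscopy
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Processing pipeline for multispectral deep-ultraviolet (UV)
    transmission microscopy of unstained tissue sections. Reads and stitches
    multichannel image cubes acquired at a small number of deep-UV wavelengths,
    converts transmission to absorbance, fits an uncentered principal-component
    spectral basis from pooled pixel spectra, represents every pixel in a
    spherical (azimuth, elevation, radius) coordinate system over principal
    component triplets, and classifies prostate tissue components (basal cells,
    inflammatory cells, luminal/fibroblast nuclei, stroma and cytoplasm) by a
    two-step angular rule with area-threshold despeckling and a morphological
    basal-cell filter. Renders virtual p63 immunohistochemistry images and
    four-channel molecular maps from the class labels. Includes a synthetic
    Beer-Lambert tissue phantom with ground-truth labels so that every stage
    of the pipeline is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    EBImage,
    tiff,
    png,
    yaml,
    jsonlite,
    stats,
    grDevices,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
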