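Package: nsctfusion
Title: Multimodal Medical Image Fusion with the Nonsubsampled Contourlet
    Transform and Pulse-Coupled Neural Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Fuses pairs of co-registered medical images (CT/MRI/PET/SPECT
    slices) by decomposing each source with a shift-invariant nonsubsampled
    contourlet transform (undecimated pyramid plus directional fan filter
    banks, 'a trous' filter upsampling), selecting each subband coefficient
    by comparing pulse-coupled neural network firing counts, and inverting
    the transform. Includes a seven-metric fusion quality suite (entropy,
    mutual information, edge-preservation Q^AB/F, PSNR, standard deviation,
    average gradient, nonlinear correlation information entropy), a
    deterministic synthetic phantom-pair generator for testing without
    clinical data, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    png,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    tiff,
    jsonlite,
    yaml,
    optparse
Config/testthat/edition: 3
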