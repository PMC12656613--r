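Package: plumgrade
Title: Multimodal Plum Quality Grading from Images and Vis/NIR Transmittance Spectra
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for non-destructive fruit quality grading that fuse RGB
    appearance features with visible/near-infrared transmittance spectra.
    Implements a weighted comprehensive quality score over normalized soluble
    solids content (SSC), peel red-colour ratio and contour circularity;
    dark-current/white-reference spectral calibration, moving-average
    denoising and O-H/C-H absorption-band selection; manual shape/colour
    descriptors and convolutional feature encoders for both modalities;
    feature-level fusion with an entropy-weighted fully connected grading
    head; evaluation metrics and an adversarial label-noise robustness
    protocol. A seeded synthetic plum generator (images, raw spectral
    triplets, SSC) makes every stage testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    EBImage,
    grDevices,
    jsonlite,
    png,
    stats,
    tools,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
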