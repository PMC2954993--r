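Package: spectrack
Title: Multispectral Cell Labeling Simulation, Unmixing and Spectral-Fingerprint Tracking
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A toolbox for multicolor nuclear cell-labeling experiments in dense
    embryonic tissue. Simulates automated object-counting accuracy as a function
    of cell density under 1-color and 3-color labeling schemes; generates
    synthetic multispectral (lambda-stack) movies of multicolor nuclear-labeled
    cells with full ground truth; performs non-negative linear unmixing of
    lambda stacks against reference spectra with background thresholding and
    maximum-intensity projection; detects and links nuclear spots with
    label-specific diameters and linking distances; and tracks cells through
    trajectory crossings using normalized per-fluorophore spectral fingerprints,
    with a spectrum-blind baseline and ground-truth evaluation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    pracma,
    EBImage,
    tiff,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    igraph,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
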