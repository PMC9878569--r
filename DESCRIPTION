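Package: fruitct
Title: Nondestructive 3D Fruit Phenotyping from Micro-CT Tomogram Stacks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for extracting morphological traits of whole fruit
    (passion fruit and similar shell-and-core fruit) from X-ray micro-CT
    tomogram stacks. Provides weak-label generation from classical image
    processing (Otsu thresholding on non-zero pixels plus area-ranked
    contour hierarchy rules), a compact U-Net style semantic segmentation
    network trained on those labels, 3D reconstruction of tri-class label
    volumes, computation of fourteen whole-fruit, sarcocarp and pericarp
    traits (volumes, surface area, length/width, shape indices, pericarp
    thickness), and cohort-level Pearson correlation, principal component
    analysis and composite quality scoring. A synthetic phantom generator
    with analytic ground truth supports end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    EBImage,
    grDevices,
    Rcpp,
    jsonlite,
    stats,
    tiff,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr (>= 3.0.0)
Config/testthat/edition: 3
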