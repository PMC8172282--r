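Package: retinaseg
Title: Retinal Vessel Segmentation by Multiscale Hessian Filtering and
    Oriented Morphology
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Unsupervised segmentation of blood vessels in colour fundus
    photographs. The pipeline extracts the green channel, enhances contrast
    with contrast-limited adaptive histogram equalization (CLAHE), computes a
    multiscale Hessian vesselness response tuned to dark tubular structures,
    cleans the response with a grayscale opening maximized over a bank of 198
    oriented linear structuring elements, and binarizes with Otsu's
    between-class-variance threshold. Includes field-of-view (FOV) mask
    estimation, accuracy/sensitivity/specificity evaluation against reference
    masks, and a seeded synthetic fundus phantom generator with known vessel
    ground truth for end-to-end testing without external datasets.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    EBImage,
    png,
    stats,
    tiff,
    yaml
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
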