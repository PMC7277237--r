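Package: molaraxis
Title: Molar Angulation Measurement from Panoramic Segmentation Masks
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Measures the long-axis angulation of mandibular molars from
    per-tooth binary segmentation masks by an iterative contour-regression
    algorithm: the contour is rotated upright, roots and occlusal surface are
    censored, and least-squares lines fitted to the mesial and distal sides
    refine the orientation over a fixed number of iterations. Includes
    segmentation evaluation metrics (IoU, precision, recall, Hausdorff
    distance), agreement statistics for paired angle measurements
    (error-interval accuracy, Bland-Altman limits of agreement, intraclass
    correlation), a third-molar eruption-potential classifier based on the
    27 degree critical angle, readers and writers for label-map PNG and
    LabelMe-style polygon annotations, and a parametric molar-phantom
    generator that produces six-tooth scenes at known ground-truth angles.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    png,
    jsonlite,
    pracma,
    EBImage,
    stats,
    utils,
    grDevices,
    graphics
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
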