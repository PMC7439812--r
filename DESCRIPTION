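Package: leafccd
Title: Leaf Shape Classification with Centroid Contour Distance Signatures
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Rotation-, scale- and translation-invariant identification of
    plant species from binary leaf silhouettes. Extracts the closed contour of
    a leaf mask, computes the normalized centroid contour distance (CCD)
    signature aligned to the farthest-point reference axis, fits a continuous
    periodic angle-to-distance curve with a Gaussian radial basis function
    network whose size, centers and spreads are tuned by a genetic algorithm,
    and resamples the curve at uniform angles to build feature vectors.
    Classifies feature vectors with a prototype RBF network, a soft-margin
    Gaussian-kernel support vector machine, and an SVM whose penalty and
    kernel width are tuned by the Salp Swarm Algorithm. Includes a synthetic
    leaf-shape generator with analytic radial-harmonic ground truth, an
    experiment driver with stratified splits and k-fold cross-validation, and
    a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    EBImage,
    e1071,
    jsonlite,
    png,
    tiff,
    yaml,
    stats,
    utils,
    graphics,
    tools
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
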