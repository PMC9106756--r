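Package: thermreg
Title: Feature-Based Nonrigid Registration of Infrared Thermal Images
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Registration pipeline for single-channel infrared (thermal)
    images dominated by flat, low-contrast regions, such as breast
    thermograms. Detects feature points in both vascular ("hot") and flat
    ("cold") patterns via Hessian eigenvalue analysis, skeletonization and
    Harris corners; matches them with per-class shape-context descriptors
    followed by two-stage iterative mismatch removal (thin-plate-spline
    coherence filtering) and pair addition; and estimates a dense
    displacement field with a match-constrained large-displacement optical
    flow solver. Includes a synthetic thermal phantom generator with
    ground-truth deformation fields, plus feature-quality and
    registration-quality metrics (spatial uniformity and sparsity entropy,
    mutual information, Canny edge overlays).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    EBImage,
    igraph,
    png,
    tiff,
    yaml,
    jsonlite,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
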