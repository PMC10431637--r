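Package: nablafuse
Title: Gradient-Domain Fusion of Multimodal Medical Images with
    Rank-Based Method Comparison
Version: 0.1.0
Authors@R:
    person("nablafuse", "developers", email = "nablafuse@example.org",
           role = c("aut", "cre"))
Description: Pixel-level fusion of co-registered single-channel medical
    images (e.g. CT and MR) in the gradient domain. Source images are
    mapped to vector fields by a discrete Nabla (central-difference)
    operator, the fields are merged by weighted-averaging, pointwise-max
    or PCA-weighted rules, and the fused image is recovered by solving
    the discrete Poisson equation with Jacobi iteration under zero
    Dirichlet boundaries. Includes objective fusion-quality metrics
    (entropy, standard deviation, average gradient, edge intensity,
    mutual information, SSIM, Qabf), a deterministic phantom generator
    for CT-like/MR-like complementary test pairs, and the full Friedman
    + critical-difference + Holm/Hochberg protocol for statistical
    comparison of fusion methods over samples-by-methods score tables.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    png,
    withr
Config/testthat/edition: 3
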