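Package: gndpca
Title: Statistical Texture Modeling of Volumetric Images by Generalized
    N-Dimensional PCA and 3D Shape Normalization
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Builds compact statistical texture models of 3D scalar volumes
    (e.g. segmented organ CT volumes) from small training cohorts.  Shape
    variability is removed by 3D shape normalization (a global rigid
    transform plus cubic-B-spline free-form deformation registered against a
    fixed reference volume); the remaining texture variation is modelled by
    generalized N-dimensional principal component analysis (GND-PCA):
    alternating estimation of per-mode orthonormal bases under Tucker's
    model, minimizing total reconstruction error over the cohort.  Core
    tensors serve as sample features; a Euclidean-distance rule against the
    training-mean feature with a largest-distance-of-training threshold
    discriminates normal from abnormal volumes.  Includes a vectorized-PCA
    (eigenface) baseline, a seeded synthetic phantom cohort generator,
    NIfTI and MetaImage volume input/output, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    RNifti,
    jsonlite,
    stats,
    graphics,
    utils
Suggests: testthat (>= 3.0.0), yaml
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
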