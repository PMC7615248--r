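Package: dia3
Title: Diffusion Anisotropy Mapping from Three Orthogonal Gradient Directions
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Computes the Diffusion Anisotropy (DiA) metric from
    diffusion-weighted MRI acquired with as few as three orthogonal
    diffusion-encoding gradient directions, together with the average
    diffusivity and an RGB orientation color code. DiA measures the distance
    from the apparent diffusion coefficient profile to its isotropic
    equivalent; the general estimator fits the profile in a real even-order
    spherical-harmonics basis with Laplace-Beltrami regularization, and a
    closed-form simplification covers the three-direction orthogonal case.
    Includes a diffusion-tensor phantom simulator (rotation schemes, Rician
    noise), gradient-scheme subsampling by angular uniformity, and drivers
    quantifying the orientation-dependent underestimation of anisotropy at
    low angular resolution. Reads and writes NIfTI-1 volumes with FSL-style
    bval/bvec gradient tables.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    EBImage,
    optparse,
    pracma,
    RNifti,
    stats,
    utils,
    withr,
    yaml
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
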