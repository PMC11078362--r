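Package: ncadyn
Title: Neural Cellular Automata for Learning Spatio-Temporal Dynamics
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Trainable neural cellular automata (NCA): a differentiable
    lattice model whose per-cell update rule is a small neural network
    acting on fixed convolution-kernel responses (identity, average,
    Sobel gradients, Laplacian). The update is learned by analytic
    backpropagation through time against trajectory snapshots, so the
    same machinery fits Turing-pattern reaction-diffusion dynamics
    (a Gray-Scott simulator is included) and image-morphing sequences
    built from synthetic raster shapes. Tools for stability analysis of
    trained rules are provided: local perturbation maps, gradient-based
    adversarial perturbation search on the kappa functional, and
    symmetry-perturbation scoring.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Matrix,
    jsonlite,
    png,
    yaml,
    stats,
    utils,
    grDevices,
    graphics
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
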