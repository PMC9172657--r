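Package: ldctgan
Title: Unpaired Low-Dose CT Denoising with a Selective-Kernel Cycle-Consistent GAN
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Trainable implementation of an unpaired low-dose CT (LDCT)
    denoising method based on a cycle-consistent generative adversarial
    network. The generator extracts features through three parallel
    branches (a residual encoder-decoder CNN, a strided U-Net and a 1x1
    convolution) fused by selective-kernel channel attention; a PatchGAN
    discriminator scores 4x4 grids of local real/fake probabilities, and
    training combines adversarial, cycle-consistency and perceptual
    losses. Includes a synthetic CT phantom and sinogram-domain low-dose
    simulator (discrete Radon transform, Poisson plus electronic noise,
    filtered back-projection), patch-based unpaired dataset construction,
    RMSE/PSNR/SSIM evaluation metrics with CT display windowing, and a
    deterministic, resumable CPU training loop.
License: MIT
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    yaml,
    png,
    tiff,
    rlang,
    stats,
    utils
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
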