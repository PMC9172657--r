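---
title: "Unpaired low-dose CT denoising with a selective-kernel CycleGAN"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Unpaired low-dose CT denoising with a selective-kernel CycleGAN}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Lowering the tube current of a CT scanner reduces patient dose but floods
the reconstruction with quantum noise and streak artifacts. Paired
training data -- the same anatomy scanned at low and normal dose -- is
rarely available in clinical practice, so supervised denoisers are often
not applicable. This package implements an *unpaired* deep-learning
denoiser: a cycle-consistent adversarial framework whose generator picks,
per feature channel, the most useful of three parallel feature extractors.

## The model

Two generators and two discriminators are trained jointly on two unpaired
image domains, low-dose $X$ and normal-dose $Y$:

* $G : X \to Y$ (the denoiser) and $F : Y \to X$ (the re-noiser);
* $D_Y$ judges whether an image looks normal-dose, $D_X$ whether it looks
  low-dose. Both are PatchGAN classifiers: six (at full scale) stride-2
  convolutions map a 256 px input to a $4\times4$ grid of sigmoid scores
  $x_{ij}$, whose mean is the discriminator output, so each score judges a
  local patch rather than the whole image.

The generator runs three branches in parallel and fuses them with
selective-kernel (SK) channel attention:

1. a RED-CNN-style residual encoder--decoder: 7 + 7 conv/deconv layers,
   $3\times3$ kernels, stride 1 throughout, with symmetric shortcut
   connections added before the deconv ReLU every other layer -- edges and
   fine structure survive because nothing is downsampled;
2. a U-Net-style branch: 7 + 7 layers with $4\times4$ kernels, stride-2
   encoder and stride-2 transposed-conv decoder with concatenation skips
   -- aggressive multi-scale noise removal at the price of detail;
3. a pointwise $1\times1$ convolution -- preserves per-pixel intensity
   information and cross-channel mixing with no spatial context.

All three produce $H \times W \times C$ maps ($C = 64$ at full scale).
They are summed, $U = U_1 + U_2 + U_3$, pooled globally per channel,
$S_c = \frac{1}{HW}\sum_{i,j} U_c(i,j)$, compacted by a learned projection
$Z = \delta(B(W_S S))$ with $\delta$ = ReLU and $B$ a normalization, and
turned into per-channel branch weights by a three-way softmax over logit
heads $A, B, C$:
$$a_c = \frac{e^{A_c Z}}{e^{A_c Z} + e^{B_c Z} + e^{C_c Z}},$$
with $a_c + b_c + c_c = 1$. The fused map is the channel-wise convex
combination $V_c = a_c U_{1,c} + b_c U_{2,c} + c_c U_{3,c}$, projected to
one channel by a final $1\times1$ convolution. Because the weights are a
softmax, $V$ always lies in the element-wise envelope of the branches --
a property the test suite checks against brute force.

The objective combines four terms,
$$\mathrm{Loss} = L_{GAN}(G, D_Y) + L_{GAN}(F, D_X) +
  \lambda\, L_{cyc}(G, F) + L_{perc},$$
with $\lambda = 10$: log-form adversarial losses for both mappings, an L1
cycle-consistency term $\|F(G(x)) - x\|_1 + \|G(F(y)) - y\|_1$, and a
perceptual term comparing frozen deep features of each image and its cycle
reconstruction at two stages of a VGG-16-topology network (the second
pooling stage, 128 channels at full width, and the last pooling stage,
512 channels).

## Design choices where the design was open

Several details are not fixed by the model description; the package makes
the following choices and keeps them stable:

* **Expectations as means.** The L1 norms in the cycle and perceptual
  terms are per-pixel (per-feature) means, not sums, so loss magnitudes
  are comparable across patch sizes.
* **Shortcut placement.** RED-CNN shortcuts connect conv layer $k$ to
  deconv layer $L - k$ for every other $k$, added before the activation.
* **SK compact feature.** $d = \max(C/2, 8)$; $B(\cdot)$ standardizes the
  $d$ components (zero mean, unit variance) with a learned gain and bias
  -- a batch-free normalization that behaves identically at batch size 1,
  which the training protocol mandates.
* **Generator adversarial direction.** For the log form, generators
  minimize $-\log D(\text{fake})$ (the non-saturating direction with the
  same fixed points as the minimax objective); a least-squares option is
  provided because log-loss cycle GANs are notoriously unstable, and is
  flagged in the config whenever enabled.
* **Perceptual extractor.** A fixed-seed randomly initialized VGG-16
  topology. Random fixed features preserve the loss's structure (distances
  in a fixed nonlinear feature space at two depths) without any
  pretrained-weight download; the tap points match the stated stages.
  Grayscale inputs are replicated to three channels.
* **Initialization.** Truncated-normal weights (sd 0.02, clipped at two
  sd), zero biases, fixed seeds everywhere -- training is bit-reproducible
  and checkpoints resume onto the identical loss trajectory.
* **Update order.** Per step: $D_Y$, $D_X$ first (one Adam update each),
  then $G$ and $F$ together on the combined objective. Eq.-style literal
  raw branch outputs $U_1..U_3$ enter the fusion (not post-sum residuals).

## The synthetic phantom study

The package carries its own data generator so the whole method is
exercisable with no external data. It emulates the clinical setting
structurally, not anatomically:

* **Phantoms**: Shepp--Logan-like ellipse composites -- an oval body,
  painted soft-tissue ellipses with attenuation drawn from $[0.3, 0.8]$,
  and optional low-intensity lung cavities, on the normalized $[0,1]$
  scale. Both display-window regimes (tissue 0.2--0.28, lung 0--0.33) show
  structure on such slices.
* **Dose**: low dose is simulated in the *sinogram* domain: a discrete
  parallel-beam Radon transform (linear splatting, 120 angles at desk
  scale), Poisson photon counts at `photons_i0` per detector bin plus
  Gaussian electronic noise (sd 2 counts), log conversion, and Ram-Lak
  filtered back-projection. This reproduces the physical mechanism of
  tube-current reduction -- correlated streak artifacts, intensity-
  dependent noise -- that image-domain white noise cannot. The default
  low-dose regime uses 600 photons/bin; the normal-dose domain uses
  $160/30 \approx 5.3$ times more (3200), mirroring a 30 mA vs 160 mA
  acquisition. At 64 px desk scale these settings put the low-dose arm at
  roughly 26 dB PSNR against the noiseless reconstruction -- visibly
  degraded, as a clinical low-dose scan is. An image-domain Gaussian mode
  (`noise_model = "gaussian"`) is kept as a fast fallback for smoke tests.
* **Patch protocol**: slices are cropped into patches on a sliding grid
  (`patch_size` 256, `stride` 16 at full scale), domain X from low-dose
  simulations of one phantom cohort, domain Y from normal-dose
  acquisitions of a *disjoint* cohort, both independently shuffled.
  Requesting overlapping cohorts is an error: it would leak pairing.
* **Paired evaluation split**: extra held-out slices from the X cohort
  keep each noisy patch aligned with its clean counterpart -- the
  noiseless filtered back-projection of the same phantom, so that paired
  metrics measure noise rather than the discretization bias shared by
  every reconstruction. Training code cannot reach this split: the
  sampler reads only the two shuffled domains, which the suite verifies.

What passing tests on phantoms do **not** show: performance on real
anatomy, scanner-specific artifact spectra (beam hardening, scatter,
helical geometry), or radiologist-perceived quality. The simulator is a
study harness, not a clinical claim.

## Desk-scale ("tiny") training profile

The full-scale protocol (batch 1, Adam, learning rate $10^{-5}$ decaying
linearly to $10^{-7}$ between steps 100k and 700k, one million steps) is
carried verbatim in the `"paper"` profile but is far outside CPU budgets.
The `"tiny"` profile scales the experiment down to minutes on one core:
64 px patches, $C = 16$, 3 + 3 RED-CNN layers, 3 U-Net stages, a 4-stage
discriminator, a 1/8-width perceptual extractor, 900 steps at the
conventional CycleGAN learning rate $2\times10^{-4}$ (decaying to
$2\times10^{-5}$ from step 360).

Compressing a million-step adversarial schedule into a thousand steps is
fragile, so the tiny profile enables a set of standard GAN stabilizers,
each exposed as an ordinary config field and all off in the full-scale
profile:

* `residual` generator head ($G(x) = x + \Delta$): starts at the identity,
  so the cycle constraint is satisfied from step 0 and adversarial
  pressure is spent on noise removal;
* `clamp_output`: generator outputs clamped to the valid $[0,1]$
  intensity range (exact subgradient). Without it the adversarial game
  can drift outside the image domain entirely -- the observed failure
  mode of unbounded heads at this scale;
* `least_squares` adversarial option evaluated on the raw (pre-sigmoid)
  score surface, the standard LSGAN formulation. Behind a sigmoid the
  least-squares gradient vanishes once the discriminator is confident,
  which at this scale produced long plateaus followed by destabilizing
  bursts; the raw-score form keeps gradients bounded and informative
  everywhere. The generators' adversarial term carries weight
  `adv_weight = 4`, calibrated so its per-pixel gradient is commensurate
  with the $\lambda/N$ scale of the per-pixel-mean cycle term;
* `d_lr_mult = 2`: discriminators learn at twice the generator rate (the
  two-time-scale rule), so the score surface tracks the generators
  rather than lagging them, plus a 25-image fake history pool;
* `ema_decay = 0.995`: inference uses an exponential moving average of
  the generator weights. Raw batch-1 adversarial trajectories oscillate;
  the averaged generator improves essentially monotonically and is what
  `denoise()` deploys.

## Metrics

RMSE, PSNR ($10\log_{10}(\mathrm{MAX}_I^2/\mathrm{MSE})$, MAX 1 on
the normalized scale) and SSIM with $k_1 = 0.01$, $k_2 = 0.02$ (note:
0.02, not the more common 0.03). SSIM statistics are computed in
$11\times11$ Gaussian-weighted sliding windows ($\sigma = 1.5$, valid
region, population moments) and averaged -- the field convention -- with
the plain global formula available via `method = "global"`. The constant
$c_3 = c_2/2$ appears only in the three-factor SSIM decomposition, which
the two-factor form in use does not need. Display windowing
(`apply_window`) is a linear rescale-and-clip used only for rendering;
no code path feeds it into losses or metrics.

## Numerical notes

* Sigmoid scores are clamped at $\varepsilon = 10^{-8}$ inside logarithms.
* Poisson draws switch to a normal approximation above $10^7$ expected
  counts (far beyond any realistic dose; keeps the noiseless-limit test
  exact to discretization error). Counts are floored at 0.5 before the
  log conversion.
* Max-pooling ties break to the first candidate in scan order;
  the degenerate $d = 1$ feature normalization returns its bias.
* A non-finite loss aborts training and dumps the step's tensors.
* All problem sizes in tests were chosen so the full suite (including two
  end-to-end tiny training runs) fits comfortably in a CPU-only session:
  gradient checks on 6--8 px tensors, simulator checks at 32--48 px, and
  the training criterion at the 64 px tiny profile.

## Known limitations

* The hand-rolled CNN stack is single-image (batch size 1 -- the
  protocol's own setting) and CPU-bound; full-scale 256 px / 64-channel
  training is supported by the code paths but not by CPU budgets.
* Parallel-beam geometry with a plain Ram-Lak filter; no beam hardening,
  scatter, or helical geometry. The simulator's purpose is a faithful
  noise *mechanism*, not a scanner model.
* With randomly initialized perceptual features the perceptual term is
  structurally faithful but numerically small; pretrained VGG-16 features
  would weight texture differently.
* DICOM input is out of scope; images travel as TIFF/PNG/CSV/RDS on the
  normalized $[0,1]$ scale.
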