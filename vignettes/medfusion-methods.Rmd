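---
title: "Unsupervised CT-MRI fusion: model, losses, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Unsupervised CT-MRI fusion: model, losses, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE, collapse = TRUE, comment = "#>")
```

## The problem

CT and T1-Gd MRI carry complementary information about the head: CT gives
geometrically faithful electron density and bright bone, MRI gives
soft-tissue and tumor contrast but no bone signal. Radiotherapy planning
workflows (IGART, stereotactic radiosurgery) want one image carrying both.
Since no ground-truth "fused" image exists, fusion is an unsupervised
learning problem. This package trains a conditional adversarial network to
map an aligned slice pair $(I_{mri}, I_{ct})$, both normalized to $[0,1]$,
to a single fused slice $I_F = G(I_{mri}, I_{ct})$.

## The model

**Generator.** A residual encoder/decoder over the 2-channel input: nine
convolution blocks, read as five down-sampling residual blocks (the first
at stride 1, the remaining four at stride 2) followed by four up-sampling
blocks, each a nearest-neighbor upsampling layer plus two residual units.
Every residual unit is convolution, batch normalization, LeakyReLU (slope
0.2), and a skip connection; a 1x1 projection aligns shapes on strided
blocks. A literal reading with five strided encoder blocks against four
decoder blocks would halve the output resolution, so the stride-1 first
block is the internally consistent reading; both counts are configurable
(`network_spec()`). The final 1-channel convolution passes through a
sigmoid so the fused image lives on the same $[0,1]$ scale as its sources.
Upsampling is nearest-neighbor followed by convolution, which avoids
checkerboard artifacts of transposed convolutions.

**Discriminator.** A PatchGAN over 2-channel concatenations: each element
of the output map judges one $M \times M$ patch, and the final score is
the arithmetic mean of the sigmoid patch map. The default stack (three
stride-2 4x4 convolutions, then two stride-1 layers) has $M = 70$;
`disc_n_layers = 2` gives $M = 34$ for 64-px training images, since $M$
must be smaller than the image. Training validates this and refuses
configurations where the patch covers the whole image.

**Adversarial value.** With $D(\cdot)$ the averaged patch score,

$$\mathcal{L}_{adv} = \log D([I_{mri}, I_{ct}]) +
  \log\!\big(1 - \lambda_1^D D([I_F, I_{mri}]) - \lambda_2^D D([I_F, I_{ct}])\big),$$

with $\lambda_1^D = \lambda_2^D = 0.5$ (the constraint
$\lambda_1^D + \lambda_2^D = 1$ is validated). The fake term is one
logarithm of the mixed score, implemented literally; both log arguments
are clamped to $[10^{-7}, 1]$ for stability. The discriminator ascends
this value. The generator's adversarial term uses the non-saturating
convention, minimizing
$-\log(\lambda_1^D D([I_F, I_{mri}]) + \lambda_2^D D([I_F, I_{ct}]))$;
the literal saturating form is available via `adv_mode = "saturating"`.

**Content losses.** The generator additionally minimizes
$\mathcal{L}_1 + \mathcal{L}_{content}$ where
$\mathcal{L}_1 = \tfrac12(\mathbb{E}|I_F - I_{mri}| + \mathbb{E}|I_F - I_{ct}|)$
and

$$\mathcal{L}_{content} =
  \lambda_1^G\, \mathbb{E}|\nabla I_F - \nabla I_{mri}| +
  \lambda_2^G\, (1 - \mathrm{SSIM}(I_F, I_{mri})) +
  \lambda_3^G\, \mathbb{E}\|\phi(I_F) - \phi(I_{ct})\|_2^2 .$$

The gradient operator is a 3x3 Sobel pair with 1-px edge-replicated
padding, the absolute difference averaged over pixels and both
components. SSIM uses the standard reference parameters
($C_1 = 0.01^2$, $C_2 = 0.03^2$ for unit dynamic range, 11x11 Gaussian
window, $\sigma = 1.5$) over fully interior windows. The perceptual
extractor $\phi$ is a frozen, seeded 3-layer convolutional stack by
default (random convolutional features are a standard, reproducible,
download-free basis for perceptual distances); a VGG16-style pretrained
stack can be supplied via `feature_extractor(mode =
"pretrained-perceptual", weights_path = ...)`.

**Content weights.** The protocol pins $\lambda_1^D, \lambda_2^D$, the
optimizer (Adam, learning rate $2 \times 10^{-4}$, here with
$\beta = (0.5, 0.999)$), batch size 8 and 40 epochs, but not the content
weights. The defaults are $\lambda_1^G = \lambda_2^G = 1$,
$\lambda_3^G = 30$. The choice is a scale balance: at initialization on
phantom pairs the MRI-side terms are of order 1 (SSIM loss $\approx 1$,
gradient loss $\approx 0.9$) while the CT-side perceptual distance is of
order $0.1$. With equal weights the generator collapses onto the MRI —
the exact single-source failure the two-fake-term discriminator is
designed to prevent — and the skull stays dark. Raising the single
CT-side weight until both pulls have the same order of magnitude (a pure
scale match suggests $\gtrsim 10$; validation on phantoms selected 30)
yields fusions with bright CT bone and MRI soft-tissue texture that track
neither source alone. All five weights are exposed in `loss_weights()`
and the config file.

## Implementation of the networks

No deep-learning framework exists in this package's dependency stack, and
the network is the method's core, so the layers are implemented directly
in R: tensors are dense `[H, W, N, C]` arrays, a $k \times k$ convolution
is computed as $k^2$ shifted BLAS matrix products, and every layer
(convolution, batch normalization in both training and inference modes,
LeakyReLU, sigmoid, nearest-neighbor upsampling, residual addition)
carries a hand-derived backward pass, assembled over a small op-graph
tape. The SSIM and Sobel losses likewise ship analytic gradients with
respect to the fused image (separable window correlations and their
adjoints). The whole composite objective is validated against central
finite differences in the test suite at relative $10^{-3}$ on sampled
parameters. Adam is implemented with bias correction; batch-norm running
statistics are frozen at inference so fusion is deterministic.

## Preprocessing

The slice-preparation pipeline is: (1) rigid co-registration of the MRI
onto the CT maximizing normalized mutual information
$\mathrm{NMI} = (H(A)+H(B))/H(A,B)$ (entropies in bits, 128 histogram
bins) over a coarse grid (rotation $\pm 15^\circ$ in $1^\circ$ steps,
integer translations $\pm 8$ px — evaluated by shifting the once-rotated
image, which is exact at integer offsets) followed by Nelder-Mead
refinement of the three continuous parameters; (2) Otsu masking of both
images (256-bin between-class-variance maximizer); (3) bed and tabletop
removal by zeroing CT pixels outside the MRI-derived head mask — the MRI
never images the table, so its mask identifies true head pixels; (4) mask
cleanup by binary closing with a disk (default radius 3 px), retaining
the largest connected component and filling holes; (5) per-slice min-max
normalization to $[0,1]$ (a constant slice maps to zeros with a warning,
since black padding slices occur); and (6) augmentation: horizontal and
vertical flips, rotation up to $20^\circ$, and 4x4 grid distortion
(node displacements up to 2 px, bilinear warp), each applied
independently with probability 0.3 and identically to both channels.
The probability is read as per-transform; registration is 2D (3 degrees
of freedom) with bilinear interpolation and zero fill, with rotations
about the image center.

A property of histogram NMI worth noting: with $B^2$ joint bins and far
fewer pixels than $B^2$, the joint entropy saturates near $\log_2 N$ and
NMI has a noticeable positive floor even for independent images. At
64x64 with 128 bins this floor is $\approx 1.16$; independence tests in
the suite therefore use more pixels and fewer bins. Registration is
unaffected — only the ranking of candidate transforms matters.

## The phantom generator

`make_phantom_pair()` emulates the contrast structure the method needs
from clinical data, not anatomy: a shared head geometry (outer skull ring
at 0.9 of the half-size, thickness 0.1); a CT channel with bone at 0.97,
low-contrast soft tissue around 0.30 ($\pm 0.05 \times$ blob field), and
an optional bright tabletop arc near the lower image border, clipped away
from the dilated head mask so the bed/head disjointness holds at every
geometry (with the default skull radius the head nearly touches the
border, so a fixed offset below the head would leave the frame); an MRI
channel with dark bone (0.02), five smoothed random ellipse regions of
distinct intensity around 0.45, and a tumor disc blended to a bright
core (0.55 + contrast, Gaussian-feathered rim, default contrast 0.3);
and independent per-channel Gaussian noise (default sd 0.02). Geometry
and noise use two independent RNG streams, so masks are reproducible
across noise realizations; every output is a pure function of
`(spec, seed, geometry_seed)`.

What the phantom does *not* emulate: anatomy, MRI physics (TE/TR/TI,
bias fields), CT beam hardening, 3D continuity, and realistic
multimodal intensity relationships. Passing tests on phantoms therefore
demonstrates the correctness and trainability of the implementation at
desk scale, not clinical image quality. One concrete consequence: the
phantom CT is nearly rotationally symmetric, so cross-modal rotation
recovery is geometrically under-determined on phantoms; registration
accuracy is therefore quantified monomodally (misaligned MRI back onto
the original MRI), while the cross-modal direction is exercised for
plumbing.

## Evaluation metrics

Nine fusion-quality metrics: Shannon entropy (256 uniform bins over
$[0,1]$, right-closed last bin), population standard deviation, mean
gradient (forward differences, $\sqrt{(\Delta_r^2 + \Delta_c^2)/2}$
averaged over interior pixels), spatial frequency
($\sqrt{RF^2 + CF^2}$ of RMS neighbor differences), mutual information
$MI(F;MRI) + MI(F;CT)$ in bits, zero-normalized cross-correlation
(averaged over the two sources), PSNR with peak 1 over the mean of the
two MSEs, the Xydeas-Petrovic edge-preservation index $Q^{XY/F}$
(Sobel strength/orientation preservation, sigmoid constants
$\Gamma = 1$, $\kappa_g = -10$, $\sigma_g = 0.5$, $\kappa_\alpha = -20$,
$\sigma_\alpha = 0.75$, saliency exponent 1, all exposed in
`qxy_params()`), and SSIM averaged over the two sources. ROI agreement
uses the Sorensen-Dice coefficient and the boundary Hausdorff distance
in mm. Method comparison uses a two-sided paired Wilcoxon signed-rank
test across slices. Every metric is pinned by an independent brute-force
oracle in the test suite; since the upstream formula sheet for these
metrics is not public, the standard fusion-literature definitions are
adopted and aggregation over the two sources (MI summed; NCC, MSE, SSIM
averaged) follows common benchmark convention.

## Desk-scale problem sizes

The test and reproduction runs use 32 phantom pairs at 64x64, batch 8,
learning rate $2\times 10^{-4}$, 200 steps, and a scaled-down network
(base width 8, three encoder blocks, two decoder blocks, $M = 34$
discriminator) — sizes chosen so a full adversarial run is a few minutes
of CPU time while still exhibiting loss descent, bone transfer, and
structural-similarity gain. The full-size defaults (base width 32, 5 + 4
blocks, $M = 70$) are what `network_spec()` produces and are intended
for real data at 256-px scale on serious hardware. Augmentation is off
in the smoke runs (it adds variance at 200-step scale) and on by default
in the CLI training path, matching the published protocol.

## Degenerate inputs and numerical conventions

Images are `[0,1]` float matrices in (row, col) order, origin top-left,
rotations counter-clockwise about the image center. Constant images:
normalization returns zeros with a warning; Otsu and NCC are undefined
and error. PSNR of an exact match is `Inf`. Log arguments in the
adversarial value are clamped at $10^{-7}$. The L1/gradient losses use
the sign subgradient at kinks. Checkpoints serialize both networks, the
optimizer state, loss weights, config and history; resuming from a
checkpoint reproduces the remaining steps bit-exactly because every
stochastic choice (shuffling, augmentation) is derived from the config
seed and the step index, never from global RNG state.

## Known limitations

- 2D slice-wise only; no 3D context or deformable registration.
- The random-feature perceptual loss is a weaker texture prior than a
  pretrained VGG16; the pretrained mode requires user-supplied weights.
- Adversarial training at 200-step desk scale is demonstrative; metric
  values on phantoms are not comparable to values reported on clinical
  data.
- The discriminator's batch statistics are updated on all three branches
  per step (real, two fakes) in a fixed order; this is deterministic but
  means batch-norm statistics see a 1:2 real:fake mix.
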