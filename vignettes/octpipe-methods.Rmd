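---
title: "octpipe: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{octpipe: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Optical coherence tomography (OCT) B-scans show the retina as a stack of
alternating hyper- and hypo-reflective horizontal layers. Three common
pathologies deform that stack in characteristic ways: choroidal
neovascularization (CNV) grows a reflective mass under it, diabetic macular
edema (DME) opens dark fluid cavities inside it, and drusen raise small
bumps on the retinal pigment epithelium (RPE) line. `octpipe` implements a
complete four-class classification pipeline for such images: classical
image enhancement, GAN-based class balancing, a compact convolutional
transformer classifier, and an evaluation harness — all runnable on one
CPU with no external deep-learning runtime.

Real clinical OCT datasets are large, external and GPU-scale to train on.
The package therefore ships a seeded phantom generator so that every stage
is exercised end to end with data whose structure (and difficulty) is
known by construction.

## The phantom generator: a stated world

A phantom is drawn once from a fixed recipe, so every test knows exactly
what signal it is looking for:

* **Bands.** `n_layers = 8` horizontal bands between 30% and 72% of the
  image height, mirroring the named retinal layers. Intensities alternate
  bright/dark on a palette spanning [40, 200], imitating the
  hyper-/hypo-reflective alternation of real scans without fitting any
  real data. Band boundaries follow a sinusoidal vertical displacement
  (`curvature = 8` px) and get a one-pixel linear blend so they are smooth
  rather than aliased.
* **Lesions.** CNV: one irregular bright mass (radius 26 px, harmonic
  boundary perturbation) below the stack. DME: five dark ellipses
  (radius 12) inside the mid bands. DRUSEN: eight bright semicircular
  bumps (radius 12) deforming the deepest band upward. Radii were chosen
  once so lesions remain visible after the 224 to 32 downsampling the
  classifier ingests (a 12 px lesion is roughly 1.7 px at 32 x 32); they
  are *not* tuned against any test outcome. The stated radii apply at the
  native 224 x 224; below that the defaults scale proportionally with the
  image side so small test renders stay geometrically valid.
* **Noise and frame.** Multiplicative speckle
  `pixel <- clip(pixel * (1 + eps), 0, 255)` with
  `eps ~ N(0, 0.1^2)` — strong enough to be visible, weak enough that
  clipping at 255 stays below ~0.3% of draws for the brightest band, so
  the sample variance of noisy/clean pixel ratios recovers `sigma^2`
  within 10%. A white 10 px frame imitates scanner-export borders.
* **Determinism.** All randomness flows through `set.seed(spec$seed)`
  with the caller's RNG state saved and restored; the same spec renders
  bit-identical images.

What a green phantom test establishes: the pipeline's mechanics (shapes,
seeding, learnability of separable-by-construction classes). What it does
not establish: clinical performance — phantoms lack speckle correlation,
shadowing, vessel artifacts, and anatomical variability of real OCT.

## Preprocessing chain

Order: white-border removal, erosion, median filter, alpha-beta
correction.

* **Border removal** is unspecified upstream beyond before/after images;
  the implementation crops (rather than zeroes) contiguous margin lines
  in which at least 90% of pixels are at or above intensity 245. Cropping
  was chosen because the published "after" image is smaller than the
  "before" image and zeroed borders would feed black frames to erosion.
* **Erosion** is a 5 x 5 grayscale minimum filter; **median** is 3 x 3 —
  the window is never stated, so the smallest standard choice is used.
  Both filters replicate edges; zero padding would create artificial dark
  borders that erosion would then spread inward.
* **Alpha-beta** is `p = clip(alpha * f + beta, 0, 255)` with
  `alpha = 1`, `beta = 2`, rounded half-up (R's `round()` rounds half to
  even, which is the wrong convention for 8-bit pixel arithmetic).
* Preprocessing applies to the union of original and GAN-generated
  images, i.e. after augmentation, matching the published methodology
  order. Whether alpha-beta precedes the 32 x 32 resize is unstated; it
  is applied before resizing here.

## DCGAN

Generator: a 100-long standard-normal latent vector, a dense projection
to `(S/16) x (S/16) x 512`, four transposed-convolution stages of widths
256/128/64/32 (kernel 4, stride 2; each followed by a leaky rectifier and
batch normalization), and a 3-channel convolution with tanh output, data
scaled to [-1, 1]. The output activation is never named upstream; tanh is
standard DCGAN practice. Discriminator: four stride-2 convolution blocks
(widths 32/64/128/256, kernel 4, LeakyReLU 0.2, dropout 0.3) and a dense
real/fake head — only the block count is published, the widths are this
package's choice. Training: Adam, learning rate 0.0008, batch 128, binary
cross-entropy, one discriminator step per generator step. The generator
trains on the standard non-saturating objective (maximize `log R(C(z))`)
because the raw minimax form stalls while the discriminator is strong;
the minimax value function is still computed and logged every step.

The acceptance smoke test runs 200 adversarial steps at `image_size = 32`
and batch 16 rather than 224/128: one 224-scale adversarial step costs
roughly 300 GFLOP and 200 of them cannot fit a CPU test budget. The
224 x 224 x 3 output geometry is verified separately on a default-size
generator. The architecture is identical up to the projection base size,
which scales as `image_size / 16`.

## The compact-transformer classifier

The classifier tokenizes a 32 x 32 x 3 image with two convolution stages
(3 -> 64 -> 128 channels, kernel 3, stride 1, each followed by ReLU and a
3 x 3 stride-2 max pool), giving g = 64 tokens of width e = 128. One
pre-norm encoder block follows — `x <- x + MSA(LN(x))`,
`x <- x + MLP(LN(x))` with a 128 -> 384 -> 128 feed-forward, ELU and
dropout 0.1 — then a final layer norm, sequence pooling, and a 4-class
softmax head. There is no positional embedding anywhere, which makes the
encoder permutation-equivariant over tokens (a property the tests
assert).

Sequence pooling replaces a class token: a learnable scoring map
`j: R^e -> R` assigns one logit per token, softmax over the g tokens
gives weights summing to one, and the pooled representation is the
weighted token sum.

**Width reconstruction.** Only parameter *budgets* are published, not the
widths. The configuration above (two-stage 64 -> 128 tokenizer, 384
feed-forward, biases everywhere, two layer norms per block plus a final
one, 128 -> 1 scoring map, 128 -> 4 head) is the unique natural
architecture that reproduces every printed budget simultaneously:
241,925 parameters (0.24 M) at one block, +165,376 per extra block
(0.41 M / 0.57 M), and 0.17 / 0.2 / 0.24 / 0.3 / 0.37 M across tokenizer
kernels 1-5. The head count (2) is parameter-neutral and unstated;
"spatial attention" is read as standard multi-head self-attention.

**Ablation grid.** 32 configurations across seven studies, each study
varying one axis while earlier winners stay fixed: encoder blocks
{1, 2, 3}; kernel {1..5}; eight activations; max/average pooling; five
optimizers; learning rates {0.01, 0.001, 0.006, 0.0008}; five losses.
The activation axis swaps the encoder-MLP activation only (the tokenizer
keeps ReLU, which is pinned by the tokenization definition). The winner
chain (1 block, kernel 3, elu, max, adam, 0.001, categorical
cross-entropy) is the package default.

## Training and evaluation harness

* **Split.** Per class, `test = round(0.3 * n)` with round-half-up; this
  reproduces all four published test counts (total 32,494) exactly.
* **Metrics.** Eleven one-vs-rest metrics per class with the standard
  formulas; MCC uses the 2 x 2 determinant form with the denominator
  factored as a product of square roots to avoid integer overflow. The
  published report never states its averaging rule, so the macro
  (unweighted) mean is the headline and a support-weighted variant is
  also emitted; zero-denominator metrics become `NA` sentinels, excluded
  from averages with a warning.
* **Cross-validation** deals shuffled per-class indices round-robin into
  k folds, so fold class proportions sit within one image of the global
  ones.
* **Reduction curve.** `size[i+1] = round(0.75 * size[i])`, 13 steps.
  Subsamples are stratified and nested (step i+1 is a subset of step i)
  so successive accuracies differ by data volume, not resampling noise.
  The published step-3 size (73,493) differs by 3 from global
  round-nearest recursion (73,490); the recursion is kept as stated and
  the discrepancy attributed to an unstated per-class rounding path.
* **Fixed-epoch protocol.** Final weights are kept; no early stopping.

## Numerical choices

* Losses act on softmax probabilities; categorical cross-entropy uses the
  exact `(p - y)/n` logit gradient, every other ablation loss is chained
  through the softmax Jacobian.
* Adam/Adamax/Nadam/RMSprop use epsilon 1e-7 and the usual bias
  corrections; Glorot-uniform initialization throughout.
* PSNR of identical images is reported as `Inf` (a sentinel, never a
  number); quality-report means are taken over finite pairs with the
  infinite count reported separately.
* SSIM follows the reference formulation: 11 x 11 Gaussian window
  (sigma 1.5), K1 = 0.01, K2 = 0.03, dynamic range 255,
  Gaussian-weighted population moments, valid-region mean. Real/synthetic
  pairs are formed by sampled order (i-th real with i-th synthetic) — a
  documented convention; no pairing rule is published.
* Image I/O: the package carries a minimal PNG codec (8-bit gray/RGB,
  zlib via `memCompress`, all five scanline filters on read) because no
  PNG package exists in the target environment; plain-text PGM/PPM are
  supported for fixtures.

## Known limitations

Phantoms are coarse archetypes, not simulations; GAN quality numbers on
phantoms say nothing about Table-level fidelity on clinical data; the
pure-R training loop is single-threaded BLAS-bound and sized for
thousands, not hundreds of thousands, of images. Reproducing the
published headline accuracies requires the external Mendeley dataset and
GPU-scale training, both out of scope by design.
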