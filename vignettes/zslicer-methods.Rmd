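---
title: "zslicer: model, numerical choices and limitations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{zslicer: model, numerical choices and limitations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(zslicer)
```

## The problem

3D fluorescence and transmitted-light microscopy stacks are almost always
anisotropic: the axial (z) sampling is several-fold coarser than the lateral
sampling, because the point spread function is elongated along the optical
axis and because finer z-stepping costs time and photon budget. Downstream
measurements — cell volumes, nuclear surface roughness, filament lengths —
inherit that anisotropy. `zslicer` densifies the z-axis computationally by
learning, from the stack collection itself, how an intermediate focal plane
looks given its two neighbours.

## Self-supervised training scheme

No annotation is used. From each high-resolution stack, triplets
`(I0, Izg, I1)` of consecutive slices are extracted
(`extract_fixed_triplets()`): the outer two are the network inputs, the
middle one is the target the network must reconstruct, at relative depth
`z = 0.5`. This is exactly the "remove every second slice" protocol: a model
that restores dropped slices from a downsampled stack will, applied to the
native stack, hallucinate plausible in-between planes.

The continuous-depth variant trains on triplets at arbitrary relative
positions `z = (n2 - n1)/(n3 - n1)` drawn within a sliding 8-slice window
(`extract_plus_triplets()`; the window tames the cubic growth of the triple
count while covering diverse `z`). The requested depth enters the network as
a constant input plane (`make_dpm()`), 0 meaning "first input plane" and 1
the second.

Paired augmentation (`augment_spec()`) applies one sampled transform —
multiplicative contrast in U(0.9, 1.1), additive brightness in U(−10, 10) on
the 8-bit scale, rotations restricted to multiples of 90° (lossless on a
square raster), horizontal flips — identically to all three planes.
The contrast/brightness ranges are package defaults (configurable); the
protocol they implement prescribes the transform families but not the
ranges. Augmentation is off by default in `train_config()` and opt-in,
because at the package's CPU-scale experiment sizes it mostly slows
convergence; at full scale it is the expected regularizer.

## Generator

Three *student* stages operate coarse-to-fine at downsample factors 4, 2, 1.
Each stage is one stride-2 3×3 convolution, `mid_convs` 3×3 convolutions
(LeakyReLU 0.2 throughout) and one 4×4 stride-2 transposed convolution
emitting 5 channels: two 2-channel flows (toward `I0` and `I1`) and one
fusion-mask logit. Stage outputs are *residual*: upsampled to full
resolution (flow values rescaled by the stage factor) and added to the
running estimate. Stage 1 sees `(I0, I1[, DPM])`; stages 2–3 see
`(I0, I1, Î_{z←0}, Î_{z←1}, M)` — the warped candidates and mask carry the
flow information forward implicitly. The synthesized frame is the convex
fusion `M ⊙ Î_{z←0} + (1 − M) ⊙ Î_{z←1}`; the mask passes through a
logistic squashing so it always lies in [0, 1].

A *teacher* stage with the same block structure — but its own weights —
additionally receives the ground-truth plane and produces refined flows, a
refined mask and a teacher frame. It exists only during training; inference
runs the student alone.

Backward warping follows the standard convention `output(p) =
image(p + flow(p))` with border-clamped bilinear sampling, so zero flow is
exactly the identity and the untrained network (whose output layers are
zero-initialized) predicts exactly the average of its two inputs — a useful
analytic baseline that several tests exploit.

### Pinned architecture and parameter counts

The full profile pins channel widths (328, 248, 160) with 6 mid
convolutions per stage, giving 10,601,463 trainable student parameters
(10.6 M), and a critic of six stride-2 4×4 convolutions with widths
(64, 136, 256, 512, 512, 512) plus a linear head on the 4×4×512 output of a
256×256 input — 11,193,289 parameters (11.19 M). The parameter count is the
architecture's published fingerprint, and the width configuration was chosen
to land it exactly; `count_parameters()` verifies both numbers by
instantiation. The reduced profile (widths 24/16/12, 2 mid convolutions,
64×64 input) preserves every structural feature at CPU scale.

## Objectives

* **Reconstruction** (`laplacian_pyramid_loss()`): mean absolute differences
  of corresponding Laplacian-pyramid components, 4 components by default
  (three band-passes + low-pass top) built with the 5-tap binomial kernel
  and equal weights. The decomposition is linear and invertible, so the loss
  vanishes iff the planes agree; at 1 level it reduces to the plain mean
  absolute error. Applied to both the student and the teacher frame (unit
  weights).
* **Distillation** (`distillation_loss()`): squared differences between each
  student stage's flows and the teacher's, summed per pixel and averaged
  over pixels (per-pixel averaging keeps `λ_d = 0.01` independent of image
  size), summed over the three stages. The teacher flow is a stop-gradient
  target — distillation transfers knowledge to the student, never the
  reverse; the finite-difference tests in `test-gradients.R` encode this
  semantics explicitly.
* **Adversarial** (optional): a Wasserstein critic (no normalization layers,
  LeakyReLU 0.2) scores realism; the generator subtracts
  `λ_adv E[D(Î_z^S)]`. The critic minimizes
  `E[D(fake)] − E[D(real)] + λ_GP E[(||∇_x D(x̃)|| − 1)²]` with `x̃` a
  uniform convex mixture of a real and a generated plane, one mixing draw
  per sample. With `λ_adv = 0` (direct mode) the critic is never built or
  evaluated — the package instruments this with an evaluation counter.

Because no autodiff framework is available in this stack, every backward
pass is derived by hand and validated against finite differences. The
gradient-penalty weight gradient is a genuine double backward: for a
piecewise-linear critic the input gradient is multilinear in the weights
(each convolution appears once, activation masks are locally constant), so
the derivative is obtained by propagating the penalty seed forward through
the adjoint of the backward chain — composed entirely from the same three
convolution kernels (forward, input-adjoint, weight-gradient).

## Training engine

Adam with the published settings (learning rate 1e-4, betas (0.5, 0.999)),
batch size 128 and 100 epochs by default; batch composition, initialization
and mixing draws are deterministic functions of the seed, and checkpoints
serialize the complete state (weights, moments, counters, RNG), so a resumed
run reproduces an unbroken one bit for bit. One critic update per generator
update by default (the adversarial weight is small, so a fully converged
critic is unnecessary); configurable. Non-finite losses abort with a
diagnostic rather than continuing silently.

A note from the package's own scaled-down experiments: raising the learning
rate to 1e-3 makes the toy configuration diverge — flows eventually escape
the warp's border-clamp region, where the warp gradient vanishes, and the
distillation term then drags the student after the runaway (stop-gradient)
teacher target. The published 1e-4 is stable, and the package keeps it for
all shipped experiments rather than introducing toy-specific tuning.

## Inference

`interpolate_pair()` min-max normalizes each input pair to the network scale
and inverts the transform on the output, so predictions live on the pair's
own intensity range (a constant pair returns itself). `double_stack()`
interleaves predictions midway into every gap — originals are preserved
byte-identically, a conservation property the tests assert — and
`augment_stack()` iterates it. `insert_slices_plus()` places predictions at
arbitrary strictly increasing depths (e.g. 0.25/0.5/0.75 for a 4-fold
densification). `bicubic_z_baseline()` provides the classical per-voxel
cubic spline along z for comparison (falling back to linear, with a warning,
below 4 slices). Planes larger than the training size are handled by
`interpolate_pair_tiled()` with end-aligned tiles and last-writer-wins
reassembly, matching the `patchify()`/`unpatchify()` round-trip contract.

## Evaluation metrics

RMSE and PSNR follow their closed forms on the 8-bit scale (identical planes
report `Inf` dB, serialized as `"inf"`). SSIM uses the reference constants —
11×11 Gaussian window (σ 1.5), k1 = 0.01, k2 = 0.03, population covariance,
valid-region averaging — and the test suite pins it to values from an
independent reference implementation to 1e-6 on deterministic fixtures. The
Fréchet distance accepts any feature embedder; the default is a seeded
random projection so analyses are self-contained and offline (its absolute
scale is therefore not comparable to published inception-based scores — use
it for within-study comparisons). `interstack_error()` scores only
synthesized slices: with stride 8, the 7 generated planes per gap.

## Surface morphometrics

For each labelled object, surface voxels are those with a six-connected
background neighbour (the tightest standard boundary); the centre is the
centroid of *all* object voxels; and the radius function `R(θ, φ)` is fitted
by least squares (uniform point weights — the projection method is a package
choice) onto real orthonormal spherical harmonics up to `lmax = 5`. The
orthonormal convention makes `f00 = ⟨R⟩ √(4π)`. The deformation power

`P_l = 4π / ((2l + 1) f00²) Σ_m f_lm²`

is scale-free and rotation-invariant, and the roughness statistic
`Ro = Σ_{l≥3} (2l + 1) P_l` excludes translation-like (l = 1) and
ellipsoidal (l = 2) modes to isolate fine-scale corrugation. The printed
source formula for `P_l` is typographically ambiguous; this reading is
isolated in `power_spectrum()` so it can be swapped in one place. Label
matching between two segmentations takes, for each label, the counterpart
with maximal voxel overlap (ties to the smaller label, deterministically),
and `compare_volumes()` tabulates conservation.

## Phantom generator

`make_phantom()` renders three sample classes: membrane *shells* (a bright
Gaussian-profile band around the surface), filled *blobs* (nuclei) and
*filament* fields (smoothed random 3D walks). Shell/blob surfaces are
`R(θ, φ) = R0 (1 + ε · 2√π · Y_lm)`, so `ε` is exactly the coefficient
ratio `f_lm / f00` the morphometrics pipeline should recover; `ε ≤ 0.3`
keeps the surface star-convex (single-valued radius), which the harmonic
fit requires. Anisotropic Gaussian blur (axial σ > lateral σ) mimics PSF
elongation; additive Gaussian noise (optionally Poisson) exercises
robustness. Everything is deterministic given the spec's seed.

What the phantoms do *not* emulate: real textured fluorophore distributions,
depth-dependent attenuation, refractive aberrations, or segmentation errors.
Tests passing on phantoms therefore demonstrate the pipeline's mechanics and
its parameter recovery on known geometry — not performance on any particular
microscope's data, which requires training on that data.

## Problem sizes in the shipped experiments

The package's own experiments are sized for a single CPU: the end-to-end
training check uses 20 shell stacks of 64×64×9 voxels (140 triplets),
batch 16, 200 iterations of the reduced profile in direct mode — enough to
halve the reconstruction loss from its analytic blend baseline — plus a
short adversarial run demonstrating finite losses and an exercised critic.
Morphometric recovery uses isotropic 64³ masks at radius 20 voxels, where
the voxelization floor of `Ro` sits below 1e-3 and a 0.1 harmonic amplitude
is recovered within 2 %. The full profile is instantiated for parameter
counting but not trained in the test suite.

## Known limitations

* Interpolation can only reuse structure present in adjacent planes: content
  thinner than the slice spacing cannot be recovered, and strong sample
  motion between slices breaks the intermediate-flow assumption.
* Two input planes only; no wider axial context.
* The roughness fit requires star-convex objects; strongly folded surfaces
  violate the single-valued radius assumption.
* The default Fréchet embedder is a random projection: distances are
  comparable within an analysis, not across publications.
* Single-device training only; no mixed precision or distribution.
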