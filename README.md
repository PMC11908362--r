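# zslicer

Self-supervised z-slice interpolation for 3D microscopy stacks.

Most 3D bio-imaging modalities resolve far less detail along the optical (z)
axis than laterally: the point spread function is axially elongated, and
phototoxicity or speed constraints force coarse z-sampling. `zslicer`
addresses this computationally. It trains a flow-based neural interpolator on
a stack collection *without any annotation*: every second slice is removed,
and the network learns to predict the missing plane from its two neighbours.
Applied iteratively, each pass converts an *n*-slice stack into a
*2n − 1*-slice stack (the last slice has no partner, hence one short of a
perfect doubling), so *k* passes yield `2^k (n − 1) + 1` slices.

The package is aimed at microscopists and image analysts who want denser
z-sampling as a preprocessing step before segmentation, rendering or
morphometric measurement, and at methodologists who want every stage of such
a pipeline exercisable and testable on synthetic data.

## The model

Given neighbouring planes `I0`, `I1`, the generator estimates intermediate
optical flows `F_{z→0}`, `F_{z→1}` and a fusion mask `M` in three
coarse-to-fine stages (downsample factors 4, 2, 1). Candidate frames are
formed by backward warping, `Î_{z←0} = W(I0, F_{z→0})` and
`Î_{z←1} = W(I1, F_{z→1})`, and fused convexly:

    Î_z = M ⊙ Î_{z←0} + (1 − M) ⊙ Î_{z←1}.

Training uses knowledge distillation: a privileged *teacher* stage that also
sees the ground-truth plane refines the flows, and the student stages are
pulled toward the teacher's flows by a distillation loss. The full objective
is

    L_G = L_rec(Î_z^S, I_z) + L_rec(Î_z^T, I_z) + λ_d L_dis − λ_adv E[D(Î_z^S)],

with Laplacian-pyramid reconstruction terms, `λ_d = 0.01`, and an optional
Wasserstein critic `D` (`λ_adv = 0.001`, or 0 for the generator-only "direct"
mode) trained with a gradient penalty (`λ_GP = 10`). Only the lightweight
student runs at inference time. A continuous-depth variant adds a constant
relative-depth input plane (each element the requested `z ∈ [0, 1]`), so
slices can be synthesized at arbitrary positions — useful for non-uniform
slice spacing.

The full-profile architecture carries 10.6 M trainable generator parameters
and 11.19 M critic parameters; a reduced profile serves CPU-scale work. All
network layers (convolutions, transposed convolutions, bilinear warping and
resizing) and their exact backward passes — including the double backward
needed for the gradient-penalty weight gradients — are implemented in
Rcpp/RcppArmadillo; no deep-learning framework is required.

Beyond the interpolator, the package ships the surrounding toolchain:
multi-page TIFF stack I/O, patch tiling, triplet extraction with paired
augmentation, image-quality metrics (RMSE, PSNR, SSIM, Fréchet distance on
pluggable embeddings), label matching and volume conservation checks,
spherical-harmonics surface-roughness analysis
(`Ro = Σ_{l≥3} (2l+1) P_l` with `P_l = 4π/((2l+1) f00²) Σ_m f_lm²`),
and a deterministic phantom generator (membrane shells, nuclei blobs,
filament fields) so everything is testable offline.

## Worked example

```r
library(zslicer)

# synthetic membrane-shell stacks with drifting centres (no external data)
testbed  <- make_interp_testbed(n_stacks = 8, seed = 7)
triplets <- unlist(lapply(testbed, function(tb)
  extract_fixed_triplets(tb$truth)), recursive = FALSE)
length(triplets)
#> [1] 56

# train the reduced-profile generator in direct mode (no critic)
cfg <- train_config(batch_size = 16, seed = 1,
                    weights = loss_weights(lambda_adv = 0),
                    net = net_config("reduced"), max_iters = 120)
state <- train(triplets, cfg)
round(state$history$Lrec[c(1, 60, 120)], 4)
#> [1] 0.0961 0.0984 0.0565          # reconstruction loss falls as flows are learned

# double a 5-slice stack and score only the 4 reconstructed slices
pair    <- testbed[[1]]$pair
doubled <- double_stack(state, pair$low_res)   # 5 -> 9 slices, originals verbatim
interstack_error(doubled, pair$full, stride = 2)
#> $rmse 20.3   $psnr 25.1   $ssim 0.776   (n_slices_evaluated = 4)

# the classical cubic z-baseline on the same stack
interstack_error(bicubic_z_baseline(pair$low_res, 2), pair$full, stride = 2)
#> $rmse 27.5   $psnr 20.4   $ssim 0.693
```

Even this 2-minute CPU training run beats cubic interpolation on every
metric: lower error (RMSE 20.3 vs 27.5), higher fidelity (PSNR 25.1 vs
20.4 dB) and better structural agreement (SSIM 0.776 vs 0.693) on the slices
that were actually synthesized.

Surface morphometrics recovers a phantom's built-in ground truth: a
nucleus-like blob with a degree-4 harmonic perturbation of relative
amplitude 0.1 yields

```r
ph  <- make_phantom(phantom_spec("blob", size = 64, n_slices = 64, dz = 1,
                                 radius = 20, noise_sd = 0, seed = 2,
                                 harmonic = list(l = 4, m = 0, eps = 0.1)))
roughness_analysis(ph$mask)[["1"]][c("mean_radius", "Ro")]
#> mean_radius 19.56    Ro 0.1307
```

while an unperturbed sphere's `Ro` sits at the discretization floor
(< 1e-3).

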