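#' Root-mean-square error between two planes
#'
#' @param a,b numeric matrices of identical shape (8-bit scale).
#' @return `sqrt(mean((a - b)^2))`, a non-negative scalar.
#' @export
rmse <- function(a, b) {
  if (!all(dim(a) == dim(b))) stop("shape mismatch")
  sqrt(mean((a - b)^2))
}

#' Peak signal-to-noise ratio in decibels
#'
#' `20 * log10(max_val / rmse)`; identical planes give `Inf` (serialized as
#' `"inf"` in JSON reports).
#'
#' @inheritParams rmse
#' @param max_val dynamic range peak (255 for 8-bit).
#' @export
psnr <- function(a, b, max_val = 255) {
  e <- rmse(a, b)
  if (e == 0) return(Inf)
  20 * log10(max_val / e)
}

# 11-tap Gaussian window, sigma 1.5 (the reference SSIM constants).
.ssim_kernel <- local({
  r <- 5L
  k1 <- exp(-(-r:r)^2 / (2 * 1.5^2))
  k1 <- k1 / sum(k1)
  K <- outer(k1, k1)
  array(K, dim = c(11L, 11L, 1L, 1L))
})

.ssim_filter <- function(x) cpp_conv2d(.as_cube(x), .ssim_kernel, 0, 1L, 0L)[, , 1]

#' Structural similarity index
#'
#' Windowed SSIM with the reference implementation's constants: 11x11 Gaussian
#' window with sigma 1.5, `k1 = 0.01`, `k2 = 0.03`, population covariances,
#' computed on the valid (fully overlapped) region and averaged.
#'
#' @inheritParams rmse
#' @param data_range dynamic range (255 for 8-bit).
#' @return A scalar in `[-1, 1]`; 1 iff the planes are identical.
#' @export
ssim <- function(a, b, data_range = 255) {
  if (!all(dim(a) == dim(b))) stop("shape mismatch")
  if (any(dim(a) < 11L)) stop("planes smaller than the 11x11 SSIM window")
  C1 <- (0.01 * data_range)^2
  C2 <- (0.03 * data_range)^2
  mu_a <- .ssim_filter(a); mu_b <- .ssim_filter(b)
  saa <- .ssim_filter(a * a) - mu_a^2
  sbb <- .ssim_filter(b * b) - mu_b^2
  sab <- .ssim_filter(a * b) - mu_a * mu_b
  s <- ((2 * mu_a * mu_b + C1) * (2 * sab + C2)) /
       ((mu_a^2 + mu_b^2 + C1) * (saa + sbb + C2))
  mean(s)
}

#' Seeded random-projection embedder for the Frechet distance
#'
#' Maps each plane to `dim` features through a fixed Gaussian random
#' projection (its own RNG stream; the global seed is untouched). A
#' self-contained stand-in for pretrained-network embeddings: distances are
#' comparable within an analysis but are not on the published inception-FID
#' scale.
#'
#' @param dim embedding dimension.
#' @param seed seed fixing the projection.
#' @return A function mapping a list of planes to an `n x dim` matrix.
#' @export
fid_embedder_random <- function(dim = 64L, seed = 20240101L) {
  force(dim); force(seed)
  function(images) {
    npix <- length(images[[1]])
    rng <- get0(".Random.seed", envir = globalenv())
    set.seed(seed)
    P <- matrix(rnorm(npix * dim, 0, 1 / sqrt(npix)), npix, dim)
    if (!is.null(rng)) assign(".Random.seed", rng, envir = globalenv())
    X <- t(vapply(images, function(im) as.numeric(im), numeric(npix)))
    X %*% P
  }
}

.mat_sqrt_sym <- function(S) {
  e <- eigen((S + t(S)) / 2, symmetric = TRUE)
  e$vectors %*% (sqrt(pmax(e$values, 0)) * t(e$vectors))
}

#' Frechet distance between two image sets
#'
#' Fits a Gaussian to each set's embedded features and returns
#' `||mu_a - mu_b||^2 + Tr(Sa + Sb - 2 (Sa Sb)^(1/2))`, the Frechet (2-
#' Wasserstein) distance between the two Gaussians. The feature embedder is
#' pluggable; the default is [fid_embedder_random()].
#'
#' @param set_a,set_b lists of planes (at least 2 each), or numeric matrices
#'   of precomputed features (rows = images).
#' @param embedder function mapping a list of planes to a feature matrix.
#' @return A non-negative scalar; 0 for identical sets.
#' @export
fid <- function(set_a, set_b, embedder = fid_embedder_random()) {
  feat <- function(s) if (is.matrix(s)) s else embedder(s)
  A <- feat(set_a); B <- feat(set_b)
  if (nrow(A) < 2L || nrow(B) < 2L) stop("need at least 2 images per set")
  mu_a <- colMeans(A); mu_b <- colMeans(B)
  Sa <- cov(A); Sb <- cov(B)
  Sa_h <- .mat_sqrt_sym(Sa)
  covmean_tr <- sum(sqrt(pmax(eigen(Sa_h %*% Sb %*% Sa_h, symmetric = TRUE,
                                    only.values = TRUE)$values, 0)))
  max(0, sum((mu_a - mu_b)^2) + sum(diag(Sa)) + sum(diag(Sb)) - 2 * covmean_tr)
}

#' Inter-stack error on generated slices only
#'
#' Evaluates a prediction stack against the ground-truth stack on generated
#' slices alone: every `stride`-th slice (1, 1+stride, ...) is an original and
#' is excluded. With stride 8 (three doubling passes) this averages over the
#' 7 generated slices in each gap.
#'
#' @param pred,truth [zstack()]s of equal length.
#' @param stride spacing of original slices in the prediction.
#' @param metrics which metrics to average.
#' @return List with the per-metric means and `n_slices_evaluated`.
#' @export
interstack_error <- function(pred, truth, stride,
                             metrics = c("rmse", "psnr", "ssim")) {
  if (n_slices(pred) != n_slices(truth)) stop("stack lengths differ")
  idx <- which((seq_len(n_slices(pred)) - 1L) %% stride != 0L)
  fns <- list(rmse = rmse, psnr = psnr, ssim = ssim)[metrics]
  out <- lapply(fns, function(f)
    mean(vapply(idx, function(i) f(get_plane(pred, i), get_plane(truth, i)), 0)))
  out$n_slices_evaluated <- length(idx)
  out
}
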