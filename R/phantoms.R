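#' Synthetic phantom specification
#'
#' Describes a deterministic synthetic 3D stack with known ground truth, used
#' to exercise every pipeline stage without external data. Three kinds mimic
#' common sample classes: `"shell"` (a bright membrane-stained surface, e.g.
#' an embryo cortex), `"blob"` (a filled nucleus-like body) and `"filaments"`
#' (smooth random 3D curves). Shell and blob surfaces are
#' `R(theta, phi) = R0 * (1 + eps * 2*sqrt(pi) * Y_lm)`, so `eps` is exactly
#' the target harmonic coefficient ratio `f_lm / f00` that the morphometrics
#' pipeline should recover. The lateral center can drift linearly with z so
#' intermediate slices are genuinely in-between their neighbours, which makes
#' midpoint prediction learnable. Anisotropic blur (axial sigma > lateral
#' sigma) mimics the axial elongation of a microscope's point spread function.
#'
#' @param kind `"shell"`, `"blob"` or `"filaments"`.
#' @param size lateral plane edge in pixels.
#' @param n_slices number of z planes (>= 3).
#' @param dz axial spacing in voxel units (1 = isotropic volume).
#' @param radius base radius `R0` in voxels (default `0.3 * size`).
#' @param thickness shell thickness parameter (voxels).
#' @param center `(y, x, z)` centre; default mid-volume.
#' @param drift lateral centre drift `(dy, dx)` per slice, voxels.
#' @param harmonic `list(l, m, eps)` surface perturbation; `eps <= 0.3` keeps
#'   the surface star-convex.
#' @param blur_sigma `(lateral, axial)` Gaussian blur sigmas in voxels.
#' @param noise_sd additive Gaussian noise sd on the 8-bit scale.
#' @param poisson also apply Poisson (shot) resampling of intensities.
#' @param n_filaments number of curves for the filament kind.
#' @param intensity peak object intensity before normalization.
#' @param seed RNG seed; phantoms are bit-reproducible given the spec.
#' @return A list of class `phantom_spec`.
#' @export
phantom_spec <- function(kind = c("shell", "blob", "filaments"),
                         size = 64L, n_slices = 9L, dz = NULL,
                         radius = NULL, thickness = 2, center = NULL,
                         drift = c(0, 0), harmonic = list(l = 0L, m = 0L, eps = 0),
                         blur_sigma = c(1, 2), noise_sd = 2, poisson = FALSE,
                         n_filaments = 8L, intensity = 200, seed = 1L) {
  kind <- match.arg(kind)
  size <- as.integer(size); n_slices <- as.integer(n_slices)
  if (is.null(radius)) radius <- 0.3 * size
  if (n_slices < 3L) stop("phantom needs at least 3 slices")
  if (is.null(dz)) dz <- if (n_slices >= size %/% 2L) 1 else
    2.2 * radius / (n_slices - 1)
  if (abs(harmonic$eps) > 0.3) stop("harmonic eps must be <= 0.3 (star-convexity)")
  if (is.null(center)) center <- c((size + 1) / 2, (size + 1) / 2, (n_slices + 1) / 2)
  if (kind != "filaments") {
    max_r <- radius * (1 + abs(harmonic$eps) * 2 * sqrt(pi))
    span <- max(abs(drift)) * n_slices / 2
    if (max_r + span >= size / 2) stop("degenerate geometry: object exceeds the volume")
  }
  structure(list(kind = kind, size = size, n_slices = n_slices, dz = dz,
                 radius = radius, thickness = thickness, center = center,
                 drift = drift, harmonic = harmonic, blur_sigma = blur_sigma,
                 noise_sd = noise_sd, poisson = poisson,
                 n_filaments = as.integer(n_filaments),
                 intensity = intensity, seed = as.integer(seed)),
            class = "phantom_spec")
}

.with_seed <- function(seed, expr) {
  old <- get0(".Random.seed", envir = globalenv())
  set.seed(seed)
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  expr
}

# separable Gaussian blur along one array axis, edge-replicated
.blur_axis <- function(a, sigma, axis) {
  if (sigma <= 0) return(a)
  r <- max(1L, ceiling(3 * sigma))
  k <- exp(-(-r:r)^2 / (2 * sigma^2)); k <- k / sum(k)
  d <- dim(a)
  out <- array(0, d)
  for (j in seq_along(k)) {
    off <- j - r - 1L
    idx <- pmin(pmax(seq_len(d[axis]) + off, 1L), d[axis])
    sl <- switch(axis, a[idx, , , drop = FALSE], a[, idx, , drop = FALSE],
                 a[, , idx, drop = FALSE])
    out <- out + k[j] * sl
  }
  out
}

#' Generate a synthetic phantom stack with ground truth
#'
#' Renders the phantom volume, applies anisotropic blur and noise, min-max
#' normalizes to 8-bit, and returns the noiseless integer label mask plus the
#' analytic surface descriptors. Deterministic given the spec (including its
#' seed).
#'
#' @param spec a [phantom_spec()].
#' @return List: `stack` (a [zstack()]), `mask` (integer array `(y, x, z)`),
#'   `descriptors` (kind, harmonic parameters, radius, per-slice centres).
#' @export
make_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  .with_seed(spec$seed, {
    d <- c(spec$size, spec$size, spec$n_slices)
    vol <- array(0, d)
    mask <- array(0L, d)
    centers <- matrix(0, spec$n_slices, 2)
    if (spec$kind %in% c("shell", "blob")) {
      yy <- matrix(seq_len(spec$size), spec$size, spec$size)
      xx <- t(yy)
      for (k in seq_len(spec$n_slices)) {
        cy <- spec$center[1] + (k - spec$center[3]) * spec$drift[1]
        cx <- spec$center[2] + (k - spec$center[3]) * spec$drift[2]
        centers[k, ] <- c(cy, cx)
        dy <- yy - cy; dx <- xx - cx; dzv <- (k - spec$center[3]) * spec$dz
        r <- sqrt(dy^2 + dx^2 + dzv^2)
        rs <- pmax(r, 1e-9)
        if (spec$harmonic$eps != 0) {
          theta <- acos(pmin(pmax(dzv / rs, -1), 1))
          phi <- atan2(dx, dy) %% (2 * pi)
          Y <- sph_harm_basis(spec$harmonic$l, theta, phi)
          col <- which(attr(Y, "l") == spec$harmonic$l & attr(Y, "m") == spec$harmonic$m)
          Rsurf <- spec$radius * (1 + spec$harmonic$eps * 2 * sqrt(pi) *
                                    matrix(Y[, col], spec$size, spec$size))
        } else Rsurf <- matrix(spec$radius, spec$size, spec$size)
        vol[, , k] <- if (spec$kind == "shell")
          spec$intensity * exp(-((r - Rsurf) / spec$thickness)^2)
        else spec$intensity * (r <= Rsurf)
        mask[, , k] <- as.integer(r <= Rsurf)
      }
    } else {
      # filaments: smooth random walks splatted with a Gaussian profile
      for (f in seq_len(spec$n_filaments)) {
        npts <- 4L * spec$size
        pos <- matrix(0, npts, 3)
        pos[1, ] <- c(runif(1, 5, spec$size - 5), runif(1, 5, spec$size - 5),
                      runif(1, 1, spec$n_slices))
        vel <- c(rnorm(2), rnorm(1, 0, 0.05))
        vel <- vel / sqrt(sum(vel^2))
        for (t in 2:npts) {
          vel <- vel + c(rnorm(2, 0, 0.15), rnorm(1, 0, 0.02))
          vel <- vel / sqrt(sum(vel^2))
          pos[t, ] <- pos[t - 1, ] + vel * 0.5
        }
        keep <- pos[, 1] >= 1 & pos[, 1] <= spec$size &
                pos[, 2] >= 1 & pos[, 2] <= spec$size &
                pos[, 3] >= 1 & pos[, 3] <= spec$n_slices
        pos <- pos[keep, , drop = FALSE]
        for (t in seq_len(nrow(pos))) {
          iy <- round(pos[t, 1]); ix <- round(pos[t, 2]); iz <- round(pos[t, 3])
          vol[iy, ix, iz] <- spec$intensity
          mask[iy, ix, iz] <- f
        }
      }
      centers <- NULL
    }
    blurred <- .blur_axis(.blur_axis(.blur_axis(vol, spec$blur_sigma[1], 1L),
                                     spec$blur_sigma[1], 2L),
                          spec$blur_sigma[2] / spec$dz, 3L)
    noisy <- blurred
    if (spec$poisson) noisy <- array(rpois(length(noisy), pmax(noisy, 0)), dim = d)
    if (spec$noise_sd > 0) noisy <- noisy + rnorm(length(noisy), 0, spec$noise_sd)
    stack <- zstack(normalize_minmax(noisy), spacing = c(spec$dz, 1, 1))
    list(stack = stack, mask = mask,
         descriptors = list(kind = spec$kind, harmonic = spec$harmonic,
                            radius = spec$radius, centers = centers, spec = spec))
  })
}

#' Split a stack into a low-resolution / full-resolution training pair
#'
#' The low-resolution stack keeps the odd slices (1, 3, 5, ...); the removed
#' even slices are the ground truth that one doubling pass must reconstruct.
#' For odd `n`, `predicted_stack_length(n_low, 1) == n` exactly.
#'
#' @param stack a [zstack()] with `n >= 3` slices.
#' @return List `low_res`, `full` (both [zstack()]).
#' @export
make_training_pair <- function(stack) {
  n <- n_slices(stack)
  if (n < 3L) stop("need at least 3 slices")
  keep <- seq(1L, n, by = 2L)
  sp <- stack$spacing
  if (!is.null(sp)) sp[1] <- sp[1] * 2
  list(low_res = zstack(stack$planes[, , keep, drop = FALSE], spacing = sp),
       full = stack)
}

#' Build a deterministic end-to-end interpolation testbed
#'
#' Generates `n_stacks` shell phantoms (64 x 64 x 9 by default) with randomly
#' drawn centres, radii and per-slice lateral drifts (at most 1 voxel per
#' slice, so intermediate slices vary smoothly and midpoint prediction is
#' learnable at toy scale), each paired with its downsampled training input.
#'
#' @param n_stacks number of phantoms.
#' @param seed master seed; each phantom derives its own sub-seed.
#' @param size,n_slices geometry forwarded to [phantom_spec()].
#' @return List of `list(pair = make_training_pair(stack), truth = stack)`.
#' @export
make_interp_testbed <- function(n_stacks = 20L, seed = 7L, size = 64L, n_slices = 9L) {
  .with_seed(seed, {
    subseeds <- sample.int(1e6, n_stacks)
    drifts <- matrix(runif(2 * n_stacks, -1, 1), ncol = 2)
    radii <- runif(n_stacks, 0.22 * size, 0.28 * size)
    lapply(seq_len(n_stacks), function(i) {
      sp <- phantom_spec("shell", size = size, n_slices = n_slices,
                         radius = radii[i], drift = drifts[i, ],
                         noise_sd = 2, seed = subseeds[i])
      ph <- make_phantom(sp)
      list(pair = make_training_pair(ph$stack), truth = ph$stack)
    })
  })
}
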