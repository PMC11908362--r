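#' Interpolate a slice between two planes
#'
#' Runs the trained student generator on one pair of 8-bit planes. The pair is
#' min-max normalized to the network scale and the transform inverted on the
#' output, so predictions live on the input pair's intensity range. The
#' fixed-midpoint variant only accepts `z = 0.5`; the continuous-z variant
#' accepts any `z` in `[0, 1]` (the constant relative-depth plane is built
#' internally).
#'
#' @param model a trained `ztrain_state`, or any list with `weights` and a
#'   [net_config()] under `config$net` (or `net`).
#' @param I0,I1 8-bit planes (matrices, identical shape).
#' @param z relative position of the requested slice.
#' @return An integer-valued matrix in `[0, 255]`.
#' @export
interpolate_pair <- function(model, I0, I1, z = 0.5) {
  mc <- .model_parts(model)
  if (!mc$config$plus && z != 0.5)
    stop("fixed-midpoint model can only interpolate at z = 0.5")
  if (!all(dim(I0) == dim(I1))) stop("plane shapes differ")
  lo <- min(I0, I1); hi <- max(I0, I1)
  if (hi == lo) return(I0)
  a0 <- (I0 - lo) / (hi - lo); a1 <- (I1 - lo) / (hi - lo)
  dpm <- if (mc$config$plus) make_dpm(z, dim(I0)) else NULL
  pred <- student_forward(a0, a1, mc$config, mc$weights, dpm = dpm)$frame
  pmin(pmax(round(pred * (hi - lo) + lo), 0), 255)
}

.model_parts <- function(model) {
  cfg <- if (inherits(model, "ztrain_state")) model$config$net
         else if (!is.null(model$net)) model$net
         else if (!is.null(model$config)) {
           if (inherits(model$config, "net_config")) model$config else model$config$net
         } else stop("cannot find a net_config in `model`")
  list(weights = model$weights, config = cfg)
}

#' Tiled prediction for planes larger than the training size
#'
#' Cuts the input pair into `patch` x `patch` tiles (end-aligned overlap on
#' non-multiple extents, as in [patchify()]), predicts each tile and
#' reassembles with last-writer-wins placement. When the plane already matches
#' the patch size this is identical to [interpolate_pair()].
#'
#' @inheritParams interpolate_pair
#' @param patch tile edge in pixels (default: the model's training input size).
#' @export
interpolate_pair_tiled <- function(model, I0, I1, z = 0.5, patch = NULL) {
  mc <- .model_parts(model)
  if (is.null(patch)) patch <- mc$config$input_size
  d <- dim(I0)
  if (all(d == patch)) return(interpolate_pair(model, I0, I1, z))
  oy <- .axis_origins(d[1], patch)
  ox <- .axis_origins(d[2], patch)
  out <- matrix(0, d[1], d[2])
  for (y in oy) for (x in ox) {
    ys <- y:(y + patch - 1L); xs <- x:(x + patch - 1L)
    out[ys, xs] <- interpolate_pair(model, I0[ys, xs], I1[ys, xs], z)
  }
  out
}

#' Slice count after iterated doubling
#'
#' One interpolation pass inserts a slice in each of the `n - 1` gaps, giving
#' `2n - 1` slices (one fewer than a perfect doubling: the last slice has no
#' partner). `k` passes give `2^k * (n - 1) + 1`.
#'
#' @param n starting slice count (`>= 2`).
#' @param k number of doubling passes (`>= 0`).
#' @return The resulting slice count.
#' @examples
#' predicted_stack_length(18, 3) # 137
#' predicted_stack_length(20, 2) # 77
#' @export
predicted_stack_length <- function(n, k) {
  if (any(n < 2)) stop("need at least 2 slices")
  if (any(k < 0)) stop("k must be >= 0")
  2^k * (n - 1) + 1
}

#' Double a stack's axial resolution
#'
#' Inserts a predicted midpoint slice into every gap: the output has `2n - 1`
#' slices, with the original slices verbatim at odd positions (1-based) and
#' predictions at even positions.
#'
#' @param model trained model (see [interpolate_pair()]).
#' @param stack an 8-bit [zstack()].
#' @return A [zstack()] with `2n - 1` slices; axial spacing metadata halved.
#' @export
double_stack <- function(model, stack) {
  n <- n_slices(stack)
  if (n < 2L) stop("need at least 2 slices")
  d <- dim(stack$planes)
  out <- array(0, c(d[1], d[2], 2L * n - 1L))
  out[, , seq(1L, 2L * n - 1L, by = 2L)] <- stack$planes
  for (i in seq_len(n - 1L))
    out[, , 2L * i] <- interpolate_pair(model, get_plane(stack, i),
                                        get_plane(stack, i + 1L), 0.5)
  sp <- stack$spacing
  if (!is.null(sp)) sp[1] <- sp[1] / 2
  zstack(out, spacing = sp)
}

#' Iterated axial doubling
#'
#' Applies [double_stack()] `k` times; the result has
#' [predicted_stack_length()]`(n, k)` slices and all original slices preserved
#' voxel-exactly.
#'
#' @inheritParams double_stack
#' @param k number of passes (`>= 1`).
#' @export
augment_stack <- function(model, stack, k) {
  if (k < 1L) stop("k must be >= 1")
  for (i in seq_len(k)) stack <- double_stack(model, stack)
  stack
}

#' Insert slices at arbitrary relative depths
#'
#' For a continuous-z model: between every adjacent slice pair, one predicted
#' slice per requested `z` is inserted in depth order. Output length is
#' `n + (n - 1) * length(zs)`; originals are preserved verbatim.
#'
#' @inheritParams double_stack
#' @param zs strictly increasing relative positions in `(0, 1)`, e.g.
#'   `c(0.25, 0.5, 0.75)`.
#' @export
insert_slices_plus <- function(model, stack, zs) {
  mc <- .model_parts(model)
  if (length(zs) == 0L) return(stack)
  if (!mc$config$plus) stop("insert_slices_plus requires a continuous-z (plus) model")
  if (any(zs <= 0) || any(zs >= 1) || is.unsorted(zs, strictly = TRUE))
    stop("zs must be strictly increasing and inside (0, 1)")
  n <- n_slices(stack)
  m <- length(zs)
  d <- dim(stack$planes)
  out <- array(0, c(d[1], d[2], n + (n - 1L) * m))
  pos <- 1L
  for (i in seq_len(n - 1L)) {
    out[, , pos] <- get_plane(stack, i)
    for (j in seq_len(m))
      out[, , pos + j] <- interpolate_pair(model, get_plane(stack, i),
                                           get_plane(stack, i + 1L), zs[j])
    pos <- pos + m + 1L
  }
  out[, , pos] <- get_plane(stack, n)
  sp <- stack$spacing
  if (!is.null(sp)) sp[1] <- sp[1] / (m + 1)
  zstack(out, spacing = sp)
}

#' Cubic interpolation along z (classical baseline)
#'
#' Interpolates each voxel column along z with a cubic spline onto the same
#' slice grid that `factor`-fold doubling would produce
#' (`factor = 2^k` inserts `2^k - 1` slices per gap). Stacks with fewer than
#' 4 slices fall back to linear interpolation with a warning.
#'
#' @param stack an 8-bit [zstack()].
#' @param factor axial magnification, a power of 2 (`>= 2`).
#' @return A [zstack()] of length [predicted_stack_length()]`(n, log2(factor))`.
#' @export
bicubic_z_baseline <- function(stack, factor = 2L) {
  k <- log2(factor)
  if (factor < 2 || k != round(k)) stop("factor must be a power of 2, >= 2")
  n <- n_slices(stack)
  zs <- seq(1, n, by = 1 / factor)
  d <- dim(stack$planes)
  linear <- n < 4L
  if (linear) warning("fewer than 4 slices: falling back to linear z-interpolation")
  # planes array is (y, x, z): columns of `flat` index voxel columns
  flat <- matrix(aperm(stack$planes, c(3, 1, 2)), nrow = d[3])
  outz <- length(zs)
  outflat <- matrix(0, outz, d[1] * d[2])
  for (j in seq_len(ncol(flat))) {
    outflat[, j] <- if (linear) approx(seq_len(n), flat[, j], xout = zs)$y
                    else spline(seq_len(n), flat[, j], xout = zs, method = "fmm")$y
  }
  out <- aperm(array(outflat, c(outz, d[1], d[2])), c(2, 3, 1))
  sp <- stack$spacing
  if (!is.null(sp)) sp[1] <- sp[1] / factor
  zstack(pmin(pmax(round(out), 0), 255), spacing = sp)
}
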