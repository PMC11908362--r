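#' Self-supervised slice triplets
#'
#' A `slice_triplet` holds two input planes `I0`, `I1`, the ground-truth
#' intermediate plane `Izg` that the interpolator must reconstruct, and the
#' relative axial position `z = (n2 - n1) / (n3 - n1)` of `Izg` between them.
#' Training data is built purely from the stack itself: slices are dropped and
#' the model is asked to predict them back.
#'
#' @name slice_triplet
NULL

.make_triplet <- function(stack, n1, n2, n3, stack_id = NA_character_) {
  structure(list(
    I0 = get_plane(stack, n1), Izg = get_plane(stack, n2), I1 = get_plane(stack, n3),
    z = unname((n2 - n1) / (n3 - n1)),
    source = list(stack_id = stack_id, indices = c(n1, n2, n3))
  ), class = "slice_triplet")
}

#' Extract fixed-midpoint training triplets
#'
#' All consecutive index triples `(i, i+1, i+2)` of a stack, each with
#' `z = 0.5`: slice `i+1` plays the ground truth for inputs `i` and `i+2`.
#' A stack of `n` slices yields `n - 2` triplets.
#'
#' @param stack a [zstack()] with uniform slice spacing.
#' @param stack_id optional identifier recorded in each triplet's source.
#' @return List of `slice_triplet` (empty when `n < 3`).
#' @export
extract_fixed_triplets <- function(stack, stack_id = NA_character_) {
  n <- n_slices(stack)
  if (n < 3L) return(list())
  lapply(seq_len(n - 2L), function(i) .make_triplet(stack, i, i + 1L, i + 2L, stack_id))
}

#' Extract arbitrary-position training triplets
#'
#' For the continuous-z variant, triplets are all strictly increasing index
#' triples `n1 < n2 < n3` drawn within a sliding window of `window` consecutive
#' slices, deduplicated across overlapping windows. The window caps the
#' combinatorial growth while keeping diverse relative positions
#' `z = (n2 - n1)/(n3 - n1)`. Stacks shorter than the window degrade to all
#' `choose(n, 3)` triples.
#'
#' @inheritParams extract_fixed_triplets
#' @param window window length in slices (default 8).
#' @return List of `slice_triplet`.
#' @export
extract_plus_triplets <- function(stack, window = 8L, stack_id = NA_character_) {
  n <- n_slices(stack)
  if (n < 3L) return(list())
  idx <- plus_triplet_indices(n, window)
  lapply(seq_len(nrow(idx)), function(k)
    .make_triplet(stack, idx[k, 1], idx[k, 2], idx[k, 3], stack_id))
}

#' Enumerate windowed triplet indices
#'
#' The index rule behind [extract_plus_triplets()], exposed for inspection:
#' unique triples `(n1, n2, n3)` with `t - window + 1 <= n1 < n2 < n3 <= t`
#' for every window end `t`.
#'
#' @param n number of slices.
#' @param window window length in slices.
#' @return Integer matrix with columns `n1, n2, n3`, lexicographically sorted.
#' @export
plus_triplet_indices <- function(n, window = 8L) {
  n <- as.integer(n); window <- as.integer(window)
  if (n < 3L) return(matrix(integer(0), 0, 3, dimnames = list(NULL, c("n1", "n2", "n3"))))
  ends <- if (n <= window) n else seq.int(window, n)
  out <- unique(do.call(rbind, lapply(ends, function(t) {
    lo <- max(1L, t - window + 1L)
    ix <- lo:t
    if (length(ix) < 3L) return(NULL)
    t(utils::combn(ix, 3L))
  })))
  out <- out[order(out[, 1], out[, 2], out[, 3]), , drop = FALSE]
  colnames(out) <- c("n1", "n2", "n3")
  out
}

#' Constant relative-depth plane (digital propagation matrix)
#'
#' A plane of constant value `z` in `[0, 1]`, concatenated as an extra input
#' channel so the continuous-z network knows the requested interpolation
#' position: 0 means "the first input focal plane", 1 the second.
#'
#' @param z relative position in `[0, 1]`.
#' @param shape integer `(ny, nx)`.
#' @return A matrix of class `dpm_plane` with attribute `z`.
#' @export
make_dpm <- function(z, shape) {
  if (!is.numeric(z) || length(z) != 1L || is.na(z) || z < 0 || z > 1)
    stop("z must be a single value in [0, 1]")
  structure(matrix(z, shape[1], shape[2]), z = z, class = c("dpm_plane", "matrix", "array"))
}

#' Paired data augmentation for triplets
#'
#' One transform is sampled per triplet and applied identically to `I0`, `Izg`
#' and `I1`: multiplicative contrast, additive brightness (8-bit scale),
#' a rotation from {0, 90, 180, 270} degrees (lossless on square rasters) and
#' an optional horizontal flip. `z` is never altered; output is clipped to
#' `[0, 255]` and rounded.
#'
#' @param triplet a `slice_triplet`.
#' @param spec an [augment_spec()].
#' @return The augmented `slice_triplet`.
#' @export
augment_triplet <- function(triplet, spec = augment_spec()) {
  stopifnot(inherits(triplet, "slice_triplet"))
  contrast <- runif(1, spec$contrast[1], spec$contrast[2])
  brightness <- runif(1, spec$brightness[1], spec$brightness[2])
  rot <- if (length(spec$rotations) == 1L) spec$rotations
         else sample(spec$rotations, 1L)
  flip <- runif(1) < spec$p_flip
  tf <- function(p) {
    p <- p * contrast + brightness
    k <- (rot %/% 90L) %% 4L
    for (i in seq_len(k)) p <- t(p)[nrow(t(p)):1, , drop = FALSE] # 90 deg ccw
    if (flip) p <- p[, ncol(p):1, drop = FALSE]
    pmin(pmax(round(p), 0), 255)
  }
  triplet$I0 <- tf(triplet$I0); triplet$Izg <- tf(triplet$Izg); triplet$I1 <- tf(triplet$I1)
  triplet
}

#' Augmentation settings
#'
#' @param contrast multiplicative factor range (default `c(0.9, 1.1)`).
#' @param brightness additive offset range on the 8-bit scale (default `c(-10, 10)`).
#' @param rotations set of allowed rotations in degrees (multiples of 90).
#' @param p_flip horizontal flip probability.
#' @return A list of class `augment_spec`.
#' @export
augment_spec <- function(contrast = c(0.9, 1.1), brightness = c(-10, 10),
                         rotations = c(0L, 90L, 180L, 270L), p_flip = 0.5) {
  stopifnot(all(rotations %% 90 == 0), p_flip >= 0, p_flip <= 1)
  structure(list(contrast = contrast, brightness = brightness,
                 rotations = as.integer(rotations), p_flip = p_flip),
            class = "augment_spec")
}

#' Identity augmentation (no-op), convenient in tests and deterministic runs.
#' @rdname augment_spec
#' @export
augment_spec_identity <- function() {
  augment_spec(contrast = c(1, 1), brightness = c(0, 0), rotations = 0L, p_flip = 0)
}

#' Write / read a triplet cache
#'
#' Serializes triplets as one TIFF per triplet (pages I0, Izg, I1) plus a
#' plain-text TSV manifest (`file, stack_id, n1, n2, n3, z`).
#'
#' @param triplets list of `slice_triplet`.
#' @param dir cache directory (created if missing).
#' @return `write_triplet_cache`: the manifest path; `read_triplet_cache`: the triplets.
#' @export
write_triplet_cache <- function(triplets, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  rows <- lapply(seq_along(triplets), function(i) {
    tr <- triplets[[i]]
    f <- sprintf("triplet_%05d.tif", i)
    write_stack(zstack(list(tr$I0, tr$Izg, tr$I1)), file.path(dir, f))
    data.frame(file = f, stack_id = tr$source$stack_id,
               n1 = tr$source$indices[1], n2 = tr$source$indices[2],
               n3 = tr$source$indices[3], z = tr$z)
  })
  manifest <- file.path(dir, "manifest.tsv")
  write.table(do.call(rbind, rows), manifest, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(manifest)
}

#' @rdname write_triplet_cache
#' @export
read_triplet_cache <- function(dir) {
  manifest <- read.delim(file.path(dir, "manifest.tsv"))
  lapply(seq_len(nrow(manifest)), function(i) {
    s <- read_stack(file.path(dir, manifest$file[i]))
    structure(list(I0 = get_plane(s, 1), Izg = get_plane(s, 2), I1 = get_plane(s, 3),
                   z = manifest$z[i],
                   source = list(stack_id = as.character(manifest$stack_id[i]),
                                 indices = c(manifest$n1[i], manifest$n2[i], manifest$n3[i]))),
              class = "slice_triplet")
  })
}
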