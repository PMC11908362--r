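#' 3D image stacks
#'
#' A `zstack` is an ordered z-series of identically shaped 2D intensity planes,
#' stored as a numeric array with dimensions `(y, x, z)` plus optional voxel
#' spacing metadata `(dz, dy, dx)` in micrometres. The working intensity range
#' is 8-bit, `[0, 255]`, after [normalize_minmax()].
#'
#' @param planes numeric array `(y, x, z)`, or a list of 2D matrices.
#' @param spacing optional numeric length-3 vector `(dz, dy, dx)` in um.
#' @return An object of class `zstack`.
#' @examples
#' s <- zstack(array(0, c(8, 8, 3)))
#' n_slices(s)
#' @export
zstack <- function(planes, spacing = NULL) {
  if (is.list(planes)) {
    shapes <- unique(lapply(planes, dim))
    if (length(shapes) != 1L) stop("all planes must share the same (y, x) shape")
    planes <- array(unlist(planes), dim = c(shapes[[1]], length(planes)))
  }
  if (!is.array(planes) || length(dim(planes)) != 3L)
    stop("planes must be a (y, x, z) array or a list of matrices")
  if (dim(planes)[3] < 2L) stop("stack needs >=2 slices")
  if (!is.null(spacing)) {
    spacing <- as.numeric(spacing)
    if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0))
      stop("spacing must be three positive numbers (dz, dy, dx)")
  }
  structure(list(planes = planes, spacing = spacing), class = "zstack")
}

#' @rdname zstack
#' @param x a `zstack`.
#' @export
n_slices <- function(x) dim(x$planes)[3]

#' @rdname zstack
#' @param i slice index (1-based).
#' @export
get_plane <- function(x, i) x$planes[, , i]

#' @export
print.zstack <- function(x, ...) {
  d <- dim(x$planes)
  cat(sprintf("<zstack> %d slices of %d x %d", d[3], d[1], d[2]))
  if (!is.null(x$spacing))
    cat(sprintf(", spacing (dz, dy, dx) = (%g, %g, %g) um", x$spacing[1], x$spacing[2], x$spacing[3]))
  cat("\n")
  invisible(x)
}

#' @export
dim.zstack <- function(x) dim(x$planes)

#' Read a multi-page TIFF z-stack
#'
#' Each TIFF page becomes one z-slice, in page order. 8- or 16-bit grayscale
#' pages are read losslessly onto their native integer scale. Voxel spacing is
#' recovered from an ImageJ-style `spacing=` description tag with x/y
#' resolution tags, or from the JSON sidecar written by [write_stack()].
#'
#' @param path path to a multi-page TIFF with at least 2 pages.
#' @return A [zstack()].
#' @export
read_stack <- function(path) {
  if (!file.exists(path)) stop("cannot read stack: no such file: ", path)
  pages <- tiff::readTIFF(path, all = TRUE, info = TRUE, as.is = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  if (length(pages) < 2L) stop("stack needs >=2 slices (file has ", length(pages), " page)")
  shapes <- unique(lapply(pages, dim))
  if (length(shapes) != 1L) stop("mixed page shapes in ", path)
  spacing <- .parse_spacing(attributes(pages[[1]]))
  if (is.null(spacing)) spacing <- .read_sidecar(path)
  zstack(lapply(pages, function(p) {
    storage.mode(p) <- "double"
    p
  }), spacing = spacing)
}

.parse_spacing <- function(att) {
  desc <- att$description
  xres <- att$x.resolution
  if (is.null(desc) || is.null(xres) || !is.numeric(xres) || xres <= 0) return(NULL)
  m <- regmatches(desc, regexec("spacing=([0-9.eE+-]+)", desc))[[1]]
  if (length(m) < 2L) return(NULL)
  dz <- suppressWarnings(as.numeric(m[2]))
  if (!isTRUE(is.finite(dz))) return(NULL)
  dxy <- 1 / xres
  c(dz, dxy, dxy)
}

.sidecar_path <- function(path) paste0(path, ".meta.json")

.read_sidecar <- function(path) {
  sc <- .sidecar_path(path)
  if (!file.exists(sc)) return(NULL)
  meta <- tryCatch(jsonlite::read_json(sc, simplifyVector = TRUE),
                   error = function(e) NULL)
  sp <- suppressWarnings(as.numeric(meta$spacing))
  if (length(sp) == 3L && all(is.finite(sp))) sp else NULL
}

#' Write a z-stack as a multi-page TIFF
#'
#' One page per slice, lossless 8-bit (or 16-bit when values exceed 255).
#' Spacing metadata, when present, is written to a small JSON sidecar
#' (`<path>.meta.json`) that [read_stack()] picks up; stacks from other tools
#' are read through their ImageJ-style TIFF description tags instead.
#'
#' @param stack a [zstack()]; values must be integers in `[0, 65535]`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_stack <- function(stack, path) {
  stopifnot(inherits(stack, "zstack"))
  if (!dir.exists(dirname(path))) stop("cannot write stack: no such directory: ", dirname(path))
  v <- stack$planes
  if (any(!is.finite(v))) stop("stack contains non-finite values")
  if (any(v < 0) || any(v != round(v))) stop("stack values must be non-negative integers")
  bits <- if (max(v) > 255) 16L else 8L
  denom <- 2^bits - 1
  pages <- lapply(seq_len(n_slices(stack)), function(i) v[, , i] / denom)
  tiff::writeTIFF(pages, path, bits.per.sample = bits, compression = "none")
  if (!is.null(stack$spacing))
    jsonlite::write_json(list(spacing = stack$spacing), .sidecar_path(path),
                         auto_unbox = FALSE, digits = NA)
  invisible(path)
}

#' Min-max normalize intensities to the 8-bit range
#'
#' Linear rescaling so the minimum maps to 0 and the maximum to 255, rounded to
#' nearest integer. For stacks the transform uses the global (per-stack) range
#' so inter-slice intensity relationships are preserved. A constant (zero
#' dynamic range) input maps to all zeros.
#'
#' @param x a [zstack()], matrix or array of finite values.
#' @return The same type, integer-valued in `[0, 255]`.
#' @examples
#' normalize_minmax(matrix(c(10, 15, 20, 20), 2))
#' @export
normalize_minmax <- function(x) {
  if (inherits(x, "zstack")) {
    x$planes <- normalize_minmax(x$planes)
    return(x)
  }
  if (any(!is.finite(x))) stop("normalize_minmax: input has NaN/Inf values")
  rng <- range(x)
  if (rng[1] == rng[2]) {
    x[] <- 0
    return(x)
  }
  x[] <- round((x - rng[1]) / (rng[2] - rng[1]) * 255)
  x
}

# Tiling rule: row-major origins every `patch` pixels; when the extent is not a
# multiple, the final origin is shifted back so the last patch end-aligns
# (overlapping its neighbour); extents smaller than the patch use edge padding.
.axis_origins <- function(extent, patch) {
  if (extent <= patch) return(1L)
  o <- seq(1L, extent - patch + 1L, by = patch)
  if (o[length(o)] != extent - patch + 1L) o <- c(o, extent - patch + 1L)
  o
}

#' Cut a stack into fixed-size lateral patches
#'
#' Tiles every plane into `patch_size` x `patch_size` patches covering the full
#' extent. Non-multiple extents end-align the last row/column of patches
#' (overlap); planes smaller than the patch are edge-padded. The returned grid
#' makes [unpatchify()] an exact inverse.
#'
#' @param stack a [zstack()].
#' @param patch_size lateral patch edge in pixels (default 256).
#' @return `list(patches = list of zstack, grid = patch_grid)`.
#' @export
patchify <- function(stack, patch_size = 256L) {
  stopifnot(inherits(stack, "zstack"))
  patch_size <- as.integer(patch_size)
  if (patch_size <= 0L) stop("patch_size must be positive")
  d <- dim(stack$planes)
  oy <- .axis_origins(d[1], patch_size)
  ox <- .axis_origins(d[2], patch_size)
  origins <- cbind(y = rep(oy, each = length(ox)), x = rep(ox, times = length(oy)))
  pady <- max(0L, patch_size - d[1])
  padx <- max(0L, patch_size - d[2])
  pl <- stack$planes
  if (pady > 0L || padx > 0L) { # replicate edge rows/cols
    iy <- pmin(seq_len(d[1] + pady), d[1])
    ix <- pmin(seq_len(d[2] + padx), d[2])
    pl <- pl[iy, ix, , drop = FALSE]
  }
  patches <- lapply(seq_len(nrow(origins)), function(k) {
    y <- origins[k, 1]; x <- origins[k, 2]
    zstack(pl[y:(y + patch_size - 1L), x:(x + patch_size - 1L), , drop = FALSE],
           spacing = stack$spacing)
  })
  grid <- structure(list(patch_size = patch_size, origins = origins,
                         shape = d[1:2], pad_mode = "edge"),
                    class = "patch_grid")
  list(patches = patches, grid = grid)
}

#' Reassemble patches produced by [patchify()]
#'
#' Patches are written back at their origins in row-major order; voxels covered
#' by several (end-aligned) patches take the last writer's value, which makes
#' `unpatchify(patchify(s))` voxel-exact.
#'
#' @param patches list of patch [zstack()]s.
#' @param grid the `patch_grid` from [patchify()].
#' @return A [zstack()] with the original plane shape.
#' @export
unpatchify <- function(patches, grid) {
  stopifnot(inherits(grid, "patch_grid"))
  if (length(patches) != nrow(grid$origins)) stop("patch count does not match grid")
  ps <- grid$patch_size
  nz <- n_slices(patches[[1]])
  full <- array(0, c(max(grid$shape[1], ps), max(grid$shape[2], ps), nz))
  for (k in seq_along(patches)) {
    p <- patches[[k]]$planes
    if (!all(dim(p) == c(ps, ps, nz))) stop("patch ", k, " does not match the grid")
    y <- grid$origins[k, 1]; x <- grid$origins[k, 2]
    full[y:(y + ps - 1L), x:(x + ps - 1L), ] <- p
  }
  zstack(full[seq_len(grid$shape[1]), seq_len(grid$shape[2]), , drop = FALSE],
         spacing = patches[[1]]$spacing)
}
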