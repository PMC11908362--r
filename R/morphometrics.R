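#' Surface point cloud of a labelled object
#'
#' Surface voxels are voxels of the label with at least one six-connected
#' background (zero or out-of-volume) neighbour. The centre is the unweighted
#' centroid of *all* the label's voxels, and each surface point carries
#' spherical coordinates `(theta, phi, R)` about it (`theta` polar from the
#' third array axis, `phi` azimuth in `[0, 2*pi)`). The harmonic fit below
#' assumes the surface is star-convex about the centre (single-valued radius).
#'
#' @param mask integer-labelled 3D array (0 = background).
#' @param label the label to extract.
#' @return A `surface_cloud`: `points` (n x 3 array-index coordinates),
#'   `center`, and `spherical` (n x 3 columns `theta, phi, R`).
#' @export
extract_surface_points <- function(mask, label) {
  if (length(dim(mask)) != 3L) stop("mask must be a 3D array")
  inside <- mask == label
  if (!any(inside)) stop("label ", label, " not present in mask")
  bg <- mask == 0
  surf <- inside & (.shift3(bg, 1, +1, TRUE) | .shift3(bg, 1, -1, TRUE) |
                    .shift3(bg, 2, +1, TRUE) | .shift3(bg, 2, -1, TRUE) |
                    .shift3(bg, 3, +1, TRUE) | .shift3(bg, 3, -1, TRUE))
  pts <- which(surf, arr.ind = TRUE)
  if (nrow(pts) < 10L)
    warning("only ", nrow(pts), " surface voxels: harmonic spectrum will be unreliable")
  center <- colMeans(which(inside, arr.ind = TRUE))
  surface_cloud(pts, center)
}

# shift a 3D logical array by one voxel along `axis`, filling with `fill`
.shift3 <- function(a, axis, dir, fill) {
  d <- dim(a)
  out <- array(fill, d)
  src <- dst <- lapply(d, seq_len)
  if (dir > 0) { dst[[axis]] <- seq_len(d[axis] - 1L); src[[axis]] <- 2:d[axis] }
  else         { dst[[axis]] <- 2:d[axis]; src[[axis]] <- seq_len(d[axis] - 1L) }
  out[dst[[1]], dst[[2]], dst[[3]]] <- a[src[[1]], src[[2]], src[[3]]]
  out
}

#' @rdname extract_surface_points
#' @param points n x 3 matrix of surface coordinates.
#' @param center length-3 centre; defaults to the points' mean.
#' @export
surface_cloud <- function(points, center = colMeans(points)) {
  points <- as.matrix(points)
  rel <- sweep(points, 2L, center)
  R <- sqrt(rowSums(rel^2))
  # a point sitting exactly on the centre (single-voxel object) is angularly
  # undefined; park it at the pole — the fit is already flagged as degenerate
  safeR <- ifelse(R > 0, R, 1)
  theta <- acos(pmin(pmax(rel[, 3] / safeR, -1), 1))
  phi <- atan2(rel[, 2], rel[, 1]) %% (2 * pi)
  structure(list(points = points, center = center,
                 spherical = cbind(theta = theta, phi = phi, R = R)),
            class = "surface_cloud")
}

# Fully normalized associated Legendre \bar P_lm(cos theta) such that the real
# harmonics Y_l0 = \bar P_l0, Y_lm = sqrt(2) \bar P_lm cos(m phi) (m > 0),
# Y_l,-m = sqrt(2) \bar P_lm sin(m phi) are orthonormal on the sphere.
.norm_plm <- function(lmax, x) {
  sx <- sqrt(pmax(0, 1 - x^2))
  P <- array(0, c(length(x), lmax + 1L, lmax + 1L))  # [point, l+1, m+1]
  P[, 1, 1] <- 1 / sqrt(4 * pi)
  if (lmax >= 1) {
    for (m in seq_len(lmax))
      P[, m + 1, m + 1] <- sqrt((2 * m + 1) / (2 * m)) * sx * P[, m, m]
    for (m in 0:(lmax - 1))
      P[, m + 2, m + 1] <- sqrt(2 * m + 3) * x * P[, m + 1, m + 1]
    if (lmax >= 2) {
      for (m in 0:(lmax - 2)) {
        for (l in (m + 2):lmax) {
          a <- sqrt((2 * l - 1) * (2 * l + 1) / ((l - m) * (l + m)))
          b <- sqrt((2 * l + 1) * (l + m - 1) * (l - m - 1) /
                    ((l - m) * (l + m) * (2 * l - 3)))
          P[, l + 1, m + 1] <- a * x * P[, l, m + 1] - b * P[, l - 1, m + 1]
        }
      }
    }
  }
  P
}

#' Real spherical harmonics (orthonormal convention)
#'
#' Evaluates the real orthonormal basis `Y_lm` (`integral(Y_lm^2) = 1` over
#' the sphere) at the given angles, for all `0 <= l <= lmax`,
#' `-l <= m <= l`. With this convention the coefficient of a constant radius
#' `R0` is `f00 = R0 * 2*sqrt(pi)` and the mean radius is
#' `f00 / sqrt(4*pi)`.
#'
#' @param lmax maximum angular degree.
#' @param theta,phi polar and azimuthal angles (radians).
#' @return Matrix `length(theta) x (lmax+1)^2`; columns ordered by `l`, then
#'   `m = -l..l`, with attributes `l` and `m`.
#' @export
sph_harm_basis <- function(lmax, theta, phi) {
  P <- .norm_plm(lmax, cos(theta))
  ncol <- (lmax + 1L)^2
  Y <- matrix(0, length(theta), ncol)
  ls <- integer(ncol); ms <- integer(ncol)
  j <- 0L
  for (l in 0:lmax) {
    for (m in (-l):l) {
      j <- j + 1L
      ls[j] <- l; ms[j] <- m
      Y[, j] <- if (m == 0) P[, l + 1, 1]
        else if (m > 0) sqrt(2) * P[, l + 1, m + 1] * cos(m * phi)
        else sqrt(2) * P[, l + 1, -m + 1] * sin(-m * phi)
    }
  }
  attr(Y, "l") <- ls; attr(Y, "m") <- ms
  Y
}

#' Fit a harmonic spectrum to a surface
#'
#' Least-squares projection of the radius function `R(theta, phi)` onto the
#' real orthonormal spherical harmonics up to degree `lmax` (uniform point
#' weighting).
#'
#' @param cloud a `surface_cloud` (or an n x 3 point matrix).
#' @param lmax maximum degree (default 5).
#' @return A `harmonic_spectrum`: data frame `coefs` (`l`, `m`, `f`), `lmax`,
#'   `f00` and the mean radius `f00 / sqrt(4*pi)`.
#' @export
fit_spherical_harmonics <- function(cloud, lmax = 5L) {
  if (!inherits(cloud, "surface_cloud")) cloud <- surface_cloud(cloud)
  sph <- cloud$spherical
  ncoef <- (lmax + 1L)^2
  if (nrow(sph) < ncoef)
    stop("need at least ", ncoef, " surface points for lmax = ", lmax)
  Y <- sph_harm_basis(lmax, sph[, "theta"], sph[, "phi"])
  qr_ <- qr(Y)
  if (qr_$rank < ncoef) stop("rank-deficient harmonic design (points too clustered)")
  f <- qr.coef(qr_, sph[, "R"])
  f00 <- f[1]
  structure(list(coefs = data.frame(l = attr(Y, "l"), m = attr(Y, "m"),
                                    f = as.numeric(f)),
                 lmax = lmax, f00 = f00, mean_radius = f00 / sqrt(4 * pi)),
            class = "harmonic_spectrum")
}

#' Power spectrum of radial deformations
#'
#' Per-degree power of the radius function, normalized by the mean radius so
#' the statistic is scale-free and rotation-invariant:
#' `P_l = 4*pi / ((2l + 1) * f00^2) * sum_m f_lm^2`. For a perfect sphere
#' `P_0 = 4*pi` and `P_l = 0` for `l >= 1`.
#'
#' @param spectrum a `harmonic_spectrum`.
#' @return Named numeric vector `P0 ... Plmax`.
#' @export
power_spectrum <- function(spectrum) {
  stopifnot(inherits(spectrum, "harmonic_spectrum"))
  if (spectrum$f00 == 0) stop("degenerate spectrum: f00 = 0")
  co <- spectrum$coefs
  vapply(0:spectrum$lmax, function(l) {
    4 * pi / ((2 * l + 1) * spectrum$f00^2) * sum(co$f[co$l == l]^2)
  }, 0) -> Pl
  names(Pl) <- paste0("P", 0:spectrum$lmax)
  Pl
}

#' Surface roughness statistic
#'
#' Total deformation power at degrees `l >= 3`:
#' `Ro = sum_{l>=3} (2l + 1) P_l`. Excluding the long-wavelength modes
#' (translation-like l = 1, ellipsoidal l = 2) isolates fine-scale roughness;
#' the statistic is invariant to rigid rotation and uniform scaling.
#'
#' @param spectrum a `harmonic_spectrum` with `lmax >= 3`.
#' @return A non-negative scalar.
#' @export
roughness <- function(spectrum) {
  stopifnot(inherits(spectrum, "harmonic_spectrum"))
  if (spectrum$lmax < 3L) stop("roughness needs lmax >= 3")
  Pl <- power_spectrum(spectrum)
  ls <- 3:spectrum$lmax
  sum((2 * ls + 1) * Pl[ls + 1L])
}

#' Match labels between two masks by maximal voxel overlap
#'
#' Each nonzero label of `mask_a` maps to the `mask_b` label with the largest
#' voxel overlap (ties broken toward the smaller b-label); labels overlapping
#' only background map to `NA`.
#'
#' @param mask_a,mask_b integer-labelled 3D arrays of identical shape.
#' @return Data frame `label_a`, `label_b`, `overlap` (voxels).
#' @export
match_labels_by_overlap <- function(mask_a, mask_b) {
  if (!all(dim(mask_a) == dim(mask_b))) stop("mask shapes differ")
  labs <- sort(unique(mask_a[mask_a != 0]))
  rows <- lapply(labs, function(la) {
    bv <- mask_b[mask_a == la]
    bv <- bv[bv != 0]
    if (length(bv) == 0L)
      return(data.frame(label_a = la, label_b = NA_integer_, overlap = 0L))
    tb <- table(bv)
    cand <- as.integer(names(tb))
    best <- which(tb == max(tb))
    pick <- best[which.min(cand[best])]
    data.frame(label_a = la, label_b = cand[pick], overlap = as.integer(tb[pick]))
  })
  do.call(rbind, rows)
}

#' Compare matched label volumes
#'
#' Voxel counts per matched label pair; unmatched labels report a b-volume of
#' zero. Volume conservation across an augmented and a ground-truth
#' segmentation indicates the interpolation preserved object geometry.
#'
#' @inheritParams match_labels_by_overlap
#' @param mapping from [match_labels_by_overlap()] (computed when `NULL`).
#' @return Data frame `label_a`, `vol_a`, `label_b`, `vol_b` (voxel counts).
#' @export
compare_volumes <- function(mask_a, mask_b, mapping = NULL) {
  if (is.null(mapping)) mapping <- match_labels_by_overlap(mask_a, mask_b)
  mapping$vol_a <- vapply(mapping$label_a, function(l) sum(mask_a == l), 0L)
  mapping$vol_b <- vapply(mapping$label_b, function(l)
    if (is.na(l)) 0L else sum(mask_b == l), 0L)
  mapping[, c("label_a", "vol_a", "label_b", "vol_b")]
}

#' One-call roughness pipeline for a labelled mask
#'
#' Surface extraction, harmonic fit, power spectrum and roughness for each
#' requested label.
#'
#' @param mask integer-labelled 3D array.
#' @param labels labels to analyse (default: all nonzero).
#' @param lmax maximum harmonic degree.
#' @return Named list per label: `f00`, `mean_radius`, `Pl`, `Ro`.
#' @export
roughness_analysis <- function(mask, labels = NULL, lmax = 5L) {
  if (is.null(labels)) labels <- sort(unique(mask[mask != 0]))
  out <- lapply(labels, function(l) {
    spec <- fit_spherical_harmonics(extract_surface_points(mask, l), lmax)
    list(f00 = spec$f00, mean_radius = spec$mean_radius,
         Pl = power_spectrum(spec), Ro = roughness(spec))
  })
  names(out) <- as.character(labels)
  out
}
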