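test_that("surface extraction finds six-connected boundary voxels", {
  m <- array(0L, c(7, 7, 7))
  m[3:5, 3:5, 3:5] <- 1L       # 3x3x3 solid cube
  cl <- extract_surface_points(m, 1)
  expect_equal(nrow(cl$points), 26L)  # all but the centre voxel
  expect_equal(unname(cl$center), c(4, 4, 4))

  single <- array(0L, c(5, 5, 5)); single[3, 3, 3] <- 7L
  expect_warning(cl1 <- extract_surface_points(single, 7), "unreliable")
  expect_equal(nrow(cl1$points), 1L)
  expect_error(extract_surface_points(m, 99), "not present")
})

test_that("digitized ball centroid sits at the true centre", {
  n <- 41
  idx <- seq_len(n) - 21
  r2 <- outer(outer(idx^2, idx^2, `+`), idx^2, `+`)
  m <- array(as.integer(r2 <= 100), c(n, n, n))   # radius 10 ball
  cl <- extract_surface_points(m, 1)
  expect_lt(max(abs(cl$center - 21)), 0.1)
})

test_that("harmonic fit recovers analytic spectra exactly", {
  th <- rep((seq_len(60) - 0.5) * pi / 60, times = 120)
  ph <- rep((seq_len(120) - 0.5) * pi / 60, each = 60)
  # constant radius 10: f00 = 10 * 2 sqrt(pi), all higher terms vanish
  pts <- cbind(10 * sin(th) * cos(ph), 10 * sin(th) * sin(ph), 10 * cos(th))
  sp <- fit_spherical_harmonics(surface_cloud(pts, center = c(0, 0, 0)), 5)
  expect_equal(sp$f00, 10 * 2 * sqrt(pi), tolerance = 1e-9)
  expect_lt(max(abs(sp$coefs$f[-1])), 1e-8)
  expect_equal(sp$mean_radius, 10, tolerance = 1e-9)

  # pure degree-2 perturbation: the fitted ratio equals amplitude / (2 sqrt(pi))
  Y <- sph_harm_basis(2, th, ph)
  y20 <- Y[, attr(Y, "l") == 2 & attr(Y, "m") == 0]
  R <- 10 * (1 + 0.1 * y20)
  pts2 <- cbind(R * sin(th) * cos(ph), R * sin(th) * sin(ph), R * cos(th))
  sp2 <- fit_spherical_harmonics(surface_cloud(pts2, center = c(0, 0, 0)), 5)
  f20 <- sp2$coefs$f[sp2$coefs$l == 2 & sp2$coefs$m == 0]
  expect_equal(f20, 10 * 0.1, tolerance = 1e-6)                  # coefficient units
  expect_equal(f20 / sp2$f00, 0.1 / (2 * sqrt(pi)), tolerance = 1e-6)
  # residual is zero for any function spanned by l <= lmax (projector property)
  fit <- sph_harm_basis(5, th, ph) %*% sp2$coefs$f
  expect_lt(max(abs(fit - R)), 1e-8)
})

test_that("power spectrum and roughness follow the normalized formulas", {
  th <- rep((seq_len(60) - 0.5) * pi / 60, times = 120)
  ph <- rep((seq_len(120) - 0.5) * pi / 60, each = 60)
  sphere <- cbind(10 * sin(th) * cos(ph), 10 * sin(th) * sin(ph), 10 * cos(th))
  sp <- fit_spherical_harmonics(surface_cloud(sphere, center = c(0, 0, 0)), 5)
  Pl <- power_spectrum(sp)
  expect_equal(unname(Pl[1]), 4 * pi)          # P0 = 4 pi by construction
  expect_lt(max(Pl[-1]), 1e-16)
  expect_equal(roughness(sp), 0, tolerance = 1e-15)

  # degree-2 deformation is excluded from Ro by design
  Y <- sph_harm_basis(2, th, ph)
  y20 <- Y[, attr(Y, "l") == 2 & attr(Y, "m") == 0]
  R2 <- 10 * (1 + 0.1 * y20)
  sp2 <- fit_spherical_harmonics(surface_cloud(
    cbind(R2 * sin(th) * cos(ph), R2 * sin(th) * sin(ph), R2 * cos(th)),
    center = c(0, 0, 0)), 5)
  expect_lt(roughness(sp2), 1e-12)
  # P2 = 4 pi / (5 f00^2) * f20^2 = (4 pi / 5) * (0.1 / (2 sqrt(pi)))^2 = 0.002
  expect_equal(unname(power_spectrum(sp2)[3]), 0.002, tolerance = 1e-6)

  # degree-4 deformation: Ro = 9 * P4, and scaling the shape changes nothing
  Y4 <- sph_harm_basis(4, th, ph)
  y40 <- Y4[, attr(Y4, "l") == 4 & attr(Y4, "m") == 0]
  R4 <- 10 * (1 + 0.05 * y40)
  pts4 <- cbind(R4 * sin(th) * cos(ph), R4 * sin(th) * sin(ph), R4 * cos(th))
  sp4 <- fit_spherical_harmonics(surface_cloud(pts4, center = c(0, 0, 0)), 5)
  Pl4 <- power_spectrum(sp4)
  expect_equal(roughness(sp4), 9 * unname(Pl4[5]), tolerance = 1e-12)
  sp4s <- fit_spherical_harmonics(surface_cloud(pts4 * 3, center = c(0, 0, 0)), 5)
  expect_equal(roughness(sp4s), roughness(sp4), tolerance = 1e-10)
  expect_error(roughness(fit_spherical_harmonics(surface_cloud(pts4, c(0, 0, 0)), 2)),
               "lmax")
})

test_that("label matching maximizes overlap with deterministic tie-breaks", {
  a <- array(0L, c(6, 6, 2)); b <- array(0L, c(6, 6, 2))
  a[1:4, 1:4, ] <- 1L
  b[1:4, 1:2, ] <- 2L   # 16 voxel overlap with a=1
  b[1:4, 3, ] <- 7L     # 8 voxel overlap
  m <- match_labels_by_overlap(a, b)
  expect_equal(m$label_b[m$label_a == 1], 2L)
  expect_equal(m$overlap[m$label_a == 1], 16L)

  # identity mapping on itself
  self <- match_labels_by_overlap(b, b)
  expect_equal(self$label_a, self$label_b)

  # disjoint masks map to nothing
  d1 <- array(0L, c(4, 4, 2)); d2 <- array(0L, c(4, 4, 2))
  d1[1, 1, 1] <- 1L; d2[4, 4, 2] <- 3L
  expect_true(is.na(match_labels_by_overlap(d1, d2)$label_b))

  # exact tie prefers the smaller b-label
  t1 <- array(0L, c(4, 4, 2)); t2 <- array(0L, c(4, 4, 2))
  t1[1:2, 1:2, 1] <- 1L
  t2[1, 1:2, 1] <- 5L; t2[2, 1:2, 1] <- 3L
  expect_equal(match_labels_by_overlap(t1, t2)$label_b, 3L)
  expect_error(match_labels_by_overlap(t1, array(0L, c(3, 3, 2))), "differ")
})

test_that("volume comparison reports matched voxel counts", {
  a <- array(0L, c(6, 6, 2)); a[1:3, 1:3, ] <- 1L; a[5:6, 5:6, ] <- 2L
  tab <- compare_volumes(a, a)
  expect_equal(tab$vol_a, tab$vol_b)
  expect_equal(tab$vol_a, c(18L, 8L))

  b <- a; b[b == 2L] <- 0L   # second object vanishes
  tab2 <- compare_volumes(a, b)
  expect_equal(tab2$vol_b[tab2$label_a == 2], 0L)
  expect_true(is.na(tab2$label_b[tab2$label_a == 2]))
})
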