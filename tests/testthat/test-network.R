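test_that("backward warping matches hand-computed bilinear samples", {
  img <- matrix(c(1, 3, 2, 4), 2) # rows y, cols x
  zero <- array(0, c(2, 2, 2))
  expect_identical(backward_warp(img, zero), img)

  # dx = 1: every pixel takes its right neighbour, right column clamps
  f <- zero; f[, , 1] <- 1
  expect_equal(backward_warp(img, f), cbind(img[, 2], img[, 2]))

  # fractional flow on a 1x2 plane [[0, 10]]: left pixel = bilinear 5
  img2 <- matrix(c(0, 10), 1)
  fh <- array(0, c(1, 2, 2)); fh[, , 1] <- 0.5
  expect_equal(backward_warp(img2, fh), matrix(c(5, 10), 1))

  # dy = 1 moves rows
  fv <- zero; fv[, , 2] <- 1
  expect_equal(backward_warp(img, fv), rbind(img[2, ], img[2, ]))
  expect_error(backward_warp(img, array(0, c(2, 2, 3))), "flow")
})

test_that("mask fusion blends convexly and validates the mask", {
  f0 <- matrix(10, 2, 2); f1 <- matrix(30, 2, 2)
  expect_equal(fuse(matrix(1, 2, 2), f0, f1), f0)
  expect_equal(fuse(matrix(0, 2, 2), f0, f1), f1)
  expect_equal(fuse(matrix(0.5, 2, 2), f0, f1), matrix(20, 2, 2))
  expect_error(fuse(matrix(1.5, 2, 2), f0, f1), "\\[0, 1\\]")
  # bounded by inputs elementwise for random masks
  set.seed(1)
  M <- matrix(runif(4), 2); a <- matrix(rnorm(4), 2); b <- matrix(rnorm(4), 2)
  out <- fuse(M, a, b)
  expect_true(all(out >= pmin(a, b) - 1e-12 & out <= pmax(a, b) + 1e-12))
})

test_that("zero-weight generator reduces to the plain average of its inputs", {
  cfg <- tiny_config()
  w <- zero_weights(cfg)
  set.seed(2)
  I0 <- matrix(runif(256), 16); I1 <- matrix(runif(256), 16)
  out <- student_forward(I0, I1, cfg, w)
  expect_equal(out$frame, 0.5 * (I0 + I1))
  expect_true(all(vapply(out$stages, function(s) all(s$flow == 0), TRUE)))
  expect_true(all(out$stages[[3]]$mask == 0.5))
  # teacher with zero weights gives the same blend
  to <- teacher_forward(I0, I1, out, matrix(runif(256), 16), cfg, w)
  expect_equal(to$teacher_frame, 0.5 * (I0 + I1))
})

test_that("generator forward contracts: shapes, determinism, variants", {
  cfg <- tiny_config()
  w <- tiny_weights(cfg, randomize_out = TRUE)
  set.seed(3)
  I0 <- matrix(runif(256), 16); I1 <- matrix(runif(256), 16); gt <- matrix(runif(256), 16)
  a <- student_forward(I0, I1, cfg, w)
  b <- student_forward(I0, I1, cfg, w)
  expect_identical(a$frame, b$frame)          # deterministic given weights
  expect_equal(dim(a$frame), dim(I0))
  expect_length(a$stages, 3L)
  expect_true(all(a$stages[[3]]$mask >= 0 & a$stages[[3]]$mask <= 1))

  to <- teacher_forward(I0, I1, a, gt, cfg, w)
  expect_equal(dim(to$teacher_frame), dim(I0))
  expect_null(a$teacher_frame)                # teacher fields absent without ground truth

  # continuous-z variant has the same I/O contract and demands its depth plane
  cfgp <- tiny_config(plus = TRUE)
  wp <- tiny_weights(cfgp, seed = 4)
  expect_error(student_forward(I0, I1, cfgp, wp), "dpm")
  outp <- student_forward(I0, I1, cfgp, wp, dpm = make_dpm(0.5, dim(I0)))
  expect_equal(dim(outp$frame), dim(I0))
  expect_error(student_forward(I0, I1, cfg, w, dpm = make_dpm(0.5, dim(I0))), "no dpm")
})

test_that("full profile reproduces the published parameter counts", {
  full <- net_config("full")
  expect_equal(round(count_parameters(full, "student"), 1), 10.6)
  expect_equal(round(count_parameters(full, "critic"), 2), 11.19)
  expect_equal(count_parameters(full, "student", millions = FALSE), 10601463)
  expect_equal(count_parameters(full, "critic", millions = FALSE), 11193289)
  red <- net_config("reduced")
  expect_lt(count_parameters(red, "student"), count_parameters(full, "student"))
  expect_lt(count_parameters(red, "critic"), count_parameters(full, "critic"))
})

test_that("critic scores are finite scalars and zero for a zero critic", {
  cfg <- tiny_config()
  set.seed(5)
  w <- init_weights(cfg, "critic")
  cr <- make_critic(w, cfg)
  x <- matrix(runif(256), 16)
  s <- critic_score(cr, x)
  expect_length(s, 1L)
  expect_true(is.finite(s))
  wz <- rapply(w, function(v) v * 0, how = "replace")
  expect_equal(critic_score(make_critic(wz, cfg), x), 0)
  g <- cr$input_grad(x)
  expect_equal(dim(g), dim(x))
  expect_true(all(is.finite(g)))
})
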