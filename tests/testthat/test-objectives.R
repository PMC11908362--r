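test_that("Laplacian pyramid loss: identity, single-level reduction, symmetry", {
  set.seed(1)
  a <- matrix(runif(1024), 32); b <- matrix(runif(1024), 32)
  expect_equal(laplacian_pyramid_loss(a, a), 0)
  expect_equal(laplacian_pyramid_loss(a, b, levels = 1), mean(abs(a - b)))
  expect_equal(laplacian_pyramid_loss(a, b), laplacian_pyramid_loss(b, a))
  expect_gt(laplacian_pyramid_loss(a, b), 0)
  expect_error(laplacian_pyramid_loss(a, matrix(0, 8, 8)), "mismatch")
})

make_stage <- function(flow) list(flow = flow)

test_that("distillation loss: zero at equality, hand value, degree-2 homogeneity", {
  F4 <- array(rnorm(4, sd = 0.1), c(1, 1, 4))
  same <- lapply(1:3, function(i) make_stage(F4))
  expect_equal(distillation_loss(same, make_stage(F4)), 0)

  # single pixel, stage-1 flow toward plane 0 differs by (1, 0): loss 1
  F1 <- F4; F1[1, 1, 1] <- F1[1, 1, 1] + 1
  stages <- list(make_stage(F1), make_stage(F4), make_stage(F4))
  expect_equal(distillation_loss(stages, make_stage(F4)), 1)

  set.seed(2)
  Fs <- lapply(1:3, function(i) make_stage(array(rnorm(8 * 8 * 4), c(8, 8, 4))))
  Ft <- make_stage(array(rnorm(8 * 8 * 4), c(8, 8, 4)))
  L1 <- distillation_loss(Fs, Ft)
  doubled <- lapply(Fs, function(s) make_stage(Ft$flow + 2 * (s$flow - Ft$flow)))
  expect_equal(distillation_loss(doubled, Ft), 4 * L1)
})

test_that("generator objective combines weighted components exactly", {
  set.seed(3)
  gt <- matrix(runif(256), 16)
  # all-perfect prediction with lambda_adv = 0 scores exactly zero
  F0 <- array(0, c(16, 16, 4))
  st <- lapply(1:3, function(i) make_stage(F0))
  rep0 <- generator_loss(gt, gt, gt, st, make_stage(F0),
                         weights = loss_weights(lambda_adv = 0))
  expect_equal(rep0$L_G, 0)

  # direct mode reduces exactly to Lrec + LrecT + lambda_d * Ldis
  ps <- matrix(runif(256), 16); pt <- matrix(runif(256), 16)
  F1 <- array(rnorm(16 * 16 * 4, sd = 0.1), c(16, 16, 4))
  st1 <- lapply(1:3, function(i) make_stage(F1 * i))
  rep1 <- generator_loss(ps, pt, gt, st1, make_stage(F1),
                         weights = loss_weights(lambda_adv = 0))
  expect_equal(rep1$L_G,
               laplacian_pyramid_loss(ps, gt) + laplacian_pyramid_loss(pt, gt) +
                 0.01 * distillation_loss(st1, make_stage(F1)))
  expect_equal(rep1$adv, 0)

  # unit components with (0.01, 0.001): 1 + 1 + 0.01 - 0.001 = 2.009
  lw <- loss_weights(lambda_d = 0.01, lambda_adv = 0.001)
  expect_equal(1 + 1 + lw$lambda_d * 1 - lw$lambda_adv * 1, 2.009)
  expect_error(loss_weights(lambda_d = -1), "non-negative")
})

test_that("gradient penalty matches the closed form for linear critics", {
  one <- matrix(0, 1, 1)
  # D(x) = sum(x) over one pixel: gradient norm exactly 1, penalty 0
  expect_equal(gradient_penalty(linear_critic(1), one, one, 0.5), 0)
  # D(x) = 2 sum(x) over 4 pixels, lambda 10: 10 * (2 * sqrt(4) - 1)^2 = 90
  four <- matrix(0, 2, 2)
  expect_equal(gradient_penalty(linear_critic(2), four, four, 0.3, 10), 90)
  # randomized oracle over coefficients and sizes; invariant to alpha
  set.seed(4)
  for (i in 1:20) {
    c0 <- runif(1, 0.1, 3); n <- sample(2:8, 1)
    real <- matrix(rnorm(n * n), n); fake <- matrix(rnorm(n * n), n)
    expected <- 10 * (c0 * n - 1)^2   # ||grad|| = c0 * sqrt(n^2)
    expect_equal(gradient_penalty(linear_critic(c0), real, fake, runif(1), 10),
                 expected)
  }
})

test_that("critic objective: cancellation, zero-critic penalty, determinism", {
  zero_critic <- list(score = function(x) 0,
                      input_grad = function(x) matrix(0, nrow(x), ncol(x)))
  batch <- lapply(1:3, function(i) matrix(runif(16), 4))
  r <- critic_loss(zero_critic, batch, batch, lambda_gp = 10)
  expect_equal(r$L_D, 10)       # scores cancel; penalty (0 - 1)^2 * 10
  # 1-Lipschitz linear critic on one pixel, identical batches: exactly zero
  b1 <- lapply(1:3, function(i) matrix(runif(1), 1))
  expect_equal(critic_loss(linear_critic(1), b1, b1, 10)$L_D, 0)
  expect_error(critic_loss(zero_critic, list(), batch), "empty")

  cfg <- tiny_config()
  set.seed(5)
  cr <- make_critic(init_weights(cfg, "critic"), cfg)
  rb <- lapply(1:2, function(i) matrix(runif(256), 16))
  fb <- lapply(1:2, function(i) matrix(runif(256), 16))
  set.seed(7); l1 <- critic_loss(cr, rb, fb)$L_D
  set.seed(7); l2 <- critic_loss(cr, rb, fb)$L_D
  expect_identical(l1, l2)
})
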