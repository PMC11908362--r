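# Finite-difference regression checks of the hand-derived backward passes.
# These guard the training engine: every analytic gradient the optimizer uses
# is compared against a numerical derivative on a small network.

ns <- asNamespace("zslicer")
fd_eps <- 1e-6

pluck <- function(x, path) { for (k in path) x <- x[[k]]; x }
poke <- function(x, path, val) {
  if (length(path) == 1L) { x[[path[[1]]]] <- val; return(x) }
  x[[path[[1]]]] <- poke(x[[path[[1]]]], path[-1], val); x
}
bump <- function(w, path, idx, eps) {
  leaf <- pluck(w, path)
  v <- do.call(`[`, c(list(leaf), as.list(idx)))
  poke(w, path, do.call(`[<-`, c(list(leaf), as.list(idx), list(v + eps))))
}

test_that("stage backward matches finite differences", {
  set.seed(10)
  st <- ns$.init_stage(5L, 8L, 2L)
  st <- rapply(st, function(x) { if (all(x == 0)) x[] <- rnorm(length(x), 0, 0.1); x },
               how = "replace")
  x <- array(rnorm(16 * 16 * 5), c(16, 16, 5))
  q4 <- array(rnorm(16 * 16 * 4), c(16, 16, 4)); q1 <- matrix(rnorm(256), 16)
  run <- function(st, x) {
    o <- ns$.stage_fwd(st, x, 2L, 0.2, with_cache = TRUE)
    list(L = sum(q4 * o$dflow) + sum(q1 * o$dlogit), cache = o$cache)
  }
  f0 <- run(st, x)
  bb <- ns$.stage_bwd(st, f0$cache, q4, q1, 0.2)
  cases <- list(list(list("conv_in", "W"), c(2, 1, 3, 4)),
                list(list("mid", 1L, "W"), c(1, 2, 3, 4)),
                list(list("mid", 2L, "b"), 5),
                list(list("out", "W"), c(2, 2, 3, 5)))
  for (cs in cases) {
    st2 <- bump(st, cs[[1]], cs[[2]], fd_eps)
    fd <- (run(st2, x)$L - f0$L) / fd_eps
    an <- do.call(`[`, c(list(pluck(bb$grads, cs[[1]])), as.list(cs[[2]])))
    expect_equal(fd, an, tolerance = 1e-4)
  }
  x2 <- x; x2[3, 9, 2] <- x2[3, 9, 2] + fd_eps
  expect_equal((run(st, x2)$L - f0$L) / fd_eps, bb$gx[3, 9, 2], tolerance = 1e-4)
})

test_that("full generator backward matches finite differences (frozen distillation target)", {
  set.seed(11)
  cfg <- tiny_config()
  w <- tiny_weights(cfg, parts = c("student", "teacher", "critic"),
                    seed = 11, randomize_out = TRUE)
  I0 <- matrix(runif(256), 16); I1 <- matrix(runif(256), 16); gt <- matrix(runif(256), 16)
  lw <- loss_weights(lambda_d = 0.01, lambda_adv = 0.001)
  base <- student_forward(I0, I1, cfg, w)
  base <- teacher_forward(I0, I1, base, gt, cfg, w)
  F4 <- base$teacher_stage$flow  # the loss treats the teacher flow as constant
  loss_fn <- function(w) {
    so <- student_forward(I0, I1, cfg, w)
    so <- teacher_forward(I0, I1, so, gt, cfg, w)
    ldis <- sum(vapply(so$stages, function(s) sum((s$flow - F4)^2) / 256, 0))
    ns$.lap_loss_grad(so$frame - gt, 4L, with_grad = FALSE)$loss +
      ns$.lap_loss_grad(so$teacher_frame - gt, 4L, with_grad = FALSE)$loss +
      lw$lambda_d * ldis -
      lw$lambda_adv * ns$.critic_fwd(so$frame, w$critic, cfg)$score
  }
  r <- ns$.generator_grads(I0, I1, gt, NULL, w, cfg, lw, 4L, critic_w = w$critic)
  expect_equal(r$L_G, loss_fn(w))
  cases <- list(list(list("stages", 1L, "conv_in", "W"), c(2, 1, 1, 3)),
                list(list("stages", 2L, "mid", 1L, "W"), c(1, 2, 3, 4)),
                list(list("stages", 3L, "out", "W"), c(2, 2, 3, 5)),
                list(list("teacher", "mid", 2L, "W"), c(3, 3, 2, 1)))
  L0 <- loss_fn(w)
  for (cs in cases) {
    fd <- (loss_fn(bump(w, cs[[1]], cs[[2]], fd_eps)) - L0) / fd_eps
    an <- do.call(`[`, c(list(pluck(r$grads, cs[[1]])), as.list(cs[[2]])))
    expect_equal(fd, an, tolerance = 1e-3)
  }
})

test_that("critic score and penalty weight gradients match finite differences", {
  set.seed(12)
  cfg <- tiny_config()
  w <- init_weights(cfg, "critic")
  x <- matrix(runif(256), 16)
  cache <- ns$.critic_fwd(x, w$critic, cfg)
  gs <- ns$.critic_score_wgrads(cache, w$critic, cfg, seed = 1)
  w2 <- w; w2$critic$convs[[2]]$W[3, 1, 4, 7] <- w2$critic$convs[[2]]$W[3, 1, 4, 7] + fd_eps
  expect_equal((ns$.critic_fwd(x, w2$critic, cfg)$score - cache$score) / fd_eps,
               gs$convs[[2]]$W[3, 1, 4, 7], tolerance = 1e-4)

  pen <- function(wc) {
    cc <- ns$.critic_fwd(x, wc, cfg)
    g <- ns$.critic_input_grad(cc, wc, cfg)$g
    10 * (sqrt(sum(g^2)) - 1)^2
  }
  r <- ns$.critic_gp_wgrads(x, w$critic, cfg, 10)
  expect_equal(r$penalty, pen(w$critic))
  for (cs in list(c(1, 2, 2, 1, 3), c(2, 3, 1, 4, 7), c(3, 1, 4, 16, 2))) {
    wp <- w$critic
    wp$convs[[cs[1]]]$W[cs[2], cs[3], cs[4], cs[5]] <-
      wp$convs[[cs[1]]]$W[cs[2], cs[3], cs[4], cs[5]] + fd_eps
    expect_equal((pen(wp) - r$penalty) / fd_eps,
                 r$grads$convs[[cs[1]]]$W[cs[2], cs[3], cs[4], cs[5]],
                 tolerance = 5e-3)
  }
})
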