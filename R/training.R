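#' Training configuration
#'
#' Defaults follow the method's published protocol: Adam with learning rate
#' `1e-4` and betas `(0.5, 0.999)`, batch size 128, 100 epochs, loss weights
#' `lambda_d = 0.01`, `lambda_adv = 0.001` (0 for the generator-only direct
#' mode) and `lambda_gp = 10`. `max_iters`, the reduced network profile and a
#' larger learning rate are the knobs for CPU-scale experiments.
#'
#' @param epochs number of passes over the triplet set.
#' @param batch_size triplets per optimization step.
#' @param lr Adam learning rate.
#' @param betas Adam `(beta1, beta2)`.
#' @param weights a [loss_weights()].
#' @param critic_steps critic updates per generator update (when adversarial).
#' @param seed RNG seed controlling init, batch order and mixing draws.
#' @param net a [net_config()].
#' @param max_iters optional hard cap on iterations (overrides `epochs`).
#' @param augment optional [augment_spec()] applied per sampled triplet.
#' @param levels pyramid components in the reconstruction losses.
#' @param checkpoint_path optional path; a checkpoint is saved each epoch.
#' @return A list of class `train_config`.
#' @export
train_config <- function(epochs = 100L, batch_size = 128L, lr = 1e-4,
                         betas = c(0.5, 0.999), weights = loss_weights(),
                         critic_steps = 1L, seed = 42L,
                         net = net_config("full"), max_iters = NULL,
                         augment = NULL, levels = 4L, checkpoint_path = NULL) {
  stopifnot(epochs >= 1L, batch_size >= 1L, lr > 0, inherits(net, "net_config"),
            inherits(weights, "loss_weights"))
  structure(list(epochs = as.integer(epochs), batch_size = as.integer(batch_size),
                 lr = lr, betas = betas, weights = weights,
                 critic_steps = as.integer(critic_steps), seed = as.integer(seed),
                 net = net, max_iters = max_iters, augment = augment,
                 levels = as.integer(levels), checkpoint_path = checkpoint_path),
            class = "train_config")
}

.zeros_like <- function(x) {
  if (is.list(x)) lapply(x, .zeros_like) else x * 0
}
.tree_add <- function(a, b) {
  if (is.list(a)) mapply(.tree_add, a, b, SIMPLIFY = FALSE) else a + b
}
.tree_scale <- function(a, s) {
  if (is.list(a)) lapply(a, .tree_scale, s = s) else a * s
}

.adam_update <- function(w, g, st, lr, b1, b2, eps = 1e-8) {
  t <- st$t + 1L
  rec <- function(w, g, m, v) {
    if (is.list(w)) {
      out <- mapply(rec, w, g, m, v, SIMPLIFY = FALSE)
      list(w = lapply(out, `[[`, "w"), m = lapply(out, `[[`, "m"),
           v = lapply(out, `[[`, "v"))
    } else {
      m2 <- b1 * m + (1 - b1) * g
      v2 <- b2 * v + (1 - b2) * g * g
      list(w = w - lr * (m2 / (1 - b1^t)) / (sqrt(v2 / (1 - b2^t)) + eps),
           m = m2, v = v2)
    }
  }
  r <- rec(w, g, st$m, st$v)
  list(w = r$w, state = list(m = r$m, v = r$v, t = t))
}

# Full backward pass of the generator objective for one sample.
# Returns weight gradients (student stages + teacher) and the loss components.
.generator_grads <- function(I0, I1, gt, dpm, weights, config, lw, levels,
                             critic_w = NULL) {
  so <- student_forward(I0, I1, config, weights, dpm = dpm, with_cache = TRUE)
  so <- teacher_forward(I0, I1, so, gt, config, weights, with_cache = TRUE)
  H <- dim(I0)[1]; W <- dim(I0)[2]; npix <- H * W
  recs <- .lap_loss_grad(so$frame - gt, levels)
  rect <- .lap_loss_grad(so$teacher_frame - gt, levels)
  ldis <- distillation_loss(so$stages, so$teacher_stage)
  adv <- 0
  gpred <- recs$grad
  if (!is.null(critic_w) && lw$lambda_adv > 0) {
    ccache <- .critic_fwd(so$frame, critic_w, config)
    adv <- ccache$score
    gpred <- gpred - lw$lambda_adv * .critic_input_grad(ccache, critic_w, config)$g
  }
  zero4 <- array(0, c(H, W, 4L)); zero1 <- matrix(0, H, W)
  gflow <- rep(list(zero4), 3L); glogit <- rep(list(zero1), 3L)
  gw0 <- rep(list(zero1), 3L); gw1 <- rep(list(zero1), 3L); gM <- rep(list(zero1), 3L)

  # student fusion
  s3 <- so$stages[[3]]; w3 <- so$warped[[3]]
  gM[[3]] <- gM[[3]] + gpred * (w3$w0 - w3$w1)
  gw0[[3]] <- gw0[[3]] + gpred * s3$mask
  gw1[[3]] <- gw1[[3]] + gpred * (1 - s3$mask)

  # teacher fusion and stage
  t4 <- so$teacher_stage; tw <- so$teacher_warped
  gM4 <- rect$grad * (tw$w0 - tw$w1)
  gw0_4 <- rect$grad * t4$mask
  gw1_4 <- rect$grad * (1 - t4$mask)
  gflow4 <- zero4
  gflow4[, , 1:2] <- cpp_warp_bwd_flow(I0, t4$flow[, , 1:2, drop = FALSE], gw0_4)
  gflow4[, , 3:4] <- cpp_warp_bwd_flow(I1, t4$flow[, , 3:4, drop = FALSE], gw1_4)
  glogit4 <- gM4 * t4$mask * (1 - t4$mask)
  tb <- .stage_bwd(weights$teacher, so$cache$teacher, gflow4, glogit4, config$leaky_slope)
  gw0[[3]] <- gw0[[3]] + tb$gx[, , 3]
  gw1[[3]] <- gw1[[3]] + tb$gx[, , 4]
  gM[[3]] <- gM[[3]] + tb$gx[, , 5]
  gflow[[3]] <- gflow[[3]] + gflow4     # residual pass-through (flow4 = flow3 + delta)
  glogit[[3]] <- glogit[[3]] + glogit4

  # distillation: teacher flow is a constant target
  for (i in 1:3)
    gflow[[i]] <- gflow[[i]] + lw$lambda_d * 2 * (so$stages[[i]]$flow - t4$flow) / npix

  stage_grads <- vector("list", 3L)
  for (i in 3:1) {
    fi <- so$stages[[i]]$flow
    gflow[[i]][, , 1:2] <- gflow[[i]][, , 1:2] +
      cpp_warp_bwd_flow(I0, fi[, , 1:2, drop = FALSE], gw0[[i]])
    gflow[[i]][, , 3:4] <- gflow[[i]][, , 3:4] +
      cpp_warp_bwd_flow(I1, fi[, , 3:4, drop = FALSE], gw1[[i]])
    glogit[[i]] <- glogit[[i]] + gM[[i]] * so$stages[[i]]$mask * (1 - so$stages[[i]]$mask)
    sb <- .stage_bwd(weights$stages[[i]], so$cache$stage[[i]],
                     gflow[[i]], glogit[[i]], config$leaky_slope)
    stage_grads[[i]] <- sb$grads
    if (i > 1L) {
      gflow[[i - 1L]] <- gflow[[i - 1L]] + gflow[[i]]
      glogit[[i - 1L]] <- glogit[[i - 1L]] + glogit[[i]]
      gw0[[i - 1L]] <- gw0[[i - 1L]] + sb$gx[, , 3]
      gw1[[i - 1L]] <- gw1[[i - 1L]] + sb$gx[, , 4]
      gM[[i - 1L]] <- gM[[i - 1L]] + sb$gx[, , 5]
    }
  }
  total <- recs$loss + rect$loss + lw$lambda_d * ldis - lw$lambda_adv * adv
  list(grads = list(stages = stage_grads, teacher = tb$grads),
       L_G = total, Lrec = recs$loss, LrecT = rect$loss, Ldis = ldis, adv = adv,
       frame = so$frame)
}

.sample_planes <- function(triplet, plus, augment) {
  if (!is.null(augment)) triplet <- augment_triplet(triplet, augment)
  list(I0 = triplet$I0 / 255, I1 = triplet$I1 / 255, gt = triplet$Izg / 255,
       dpm = if (plus) make_dpm(triplet$z, dim(triplet$I0)) else NULL)
}

.init_train_state <- function(config, triplets) {
  set.seed(config$seed)
  parts <- c("student", "teacher")
  if (config$weights$lambda_adv > 0) parts <- c(parts, "critic")
  w <- init_weights(config$net, parts = parts)
  st <- list(weights = w, config = config,
             adam_g = list(m = .zeros_like(w[c("stages", "teacher")]),
                           v = .zeros_like(w[c("stages", "teacher")]), t = 0L),
             adam_c = if (!is.null(w$critic))
               list(m = .zeros_like(w["critic"]), v = .zeros_like(w["critic"]), t = 0L),
             iter = 0L, epoch = 0L, critic_evals = 0L,
             history = NULL)
  class(st) <- "ztrain_state"
  st
}

.check_arch_match <- function(weights, config) {
  got <- dim(weights$stages[[1]]$conv_in$W)[4]
  if (got != config$net$channels[1])
    stop("checkpoint architecture mismatch: stage-1 width ", got,
         " vs configured ", config$net$channels[1])
}

.train_loop <- function(state, triplets, n_iters) {
  n_iters <- as.integer(n_iters)
  config <- state$config
  lw <- config$weights
  plus <- config$net$plus
  n <- length(triplets)
  iters_per_epoch <- max(1L, ceiling(n / config$batch_size))
  logs <- vector("list", n_iters)
  for (it in seq_len(n_iters)) {
    idx <- sample.int(n, min(config$batch_size, n))
    batch <- lapply(triplets[idx], .sample_planes, plus = plus, augment = config$augment)

    L_D <- NA_real_; gp_mean <- NA_real_
    if (lw$lambda_adv > 0) {
      for (cs in seq_len(config$critic_steps)) {
        cw <- state$weights$critic
        cgrads <- NULL; fsum <- 0; rsum <- 0; gpsum <- 0
        B <- length(batch)
        for (s in batch) {
          fake <- student_forward(s$I0, s$I1, config$net, state$weights,
                                  dpm = s$dpm)$frame
          cf <- .critic_fwd(fake, cw, config$net)
          cr <- .critic_fwd(s$gt, cw, config$net)
          fsum <- fsum + cf$score; rsum <- rsum + cr$score
          g1 <- .critic_score_wgrads(cf, cw, config$net, seed = 1 / B)
          g2 <- .critic_score_wgrads(cr, cw, config$net, seed = -1 / B)
          alpha <- runif(1)
          gpq <- .critic_gp_wgrads(alpha * s$gt + (1 - alpha) * fake, cw, config$net,
                                   lw$lambda_gp)
          gpsum <- gpsum + gpq$penalty
          gi <- .tree_add(.tree_add(g1, g2), .tree_scale(gpq$grads, 1 / B))
          cgrads <- if (is.null(cgrads)) gi else .tree_add(cgrads, gi)
          state$critic_evals <- state$critic_evals + 3L
        }
        L_D <- (fsum - rsum + gpsum) / B
        gp_mean <- gpsum / B
        upd <- .adam_update(state$weights["critic"], list(critic = cgrads),
                            state$adam_c, config$lr, config$betas[1], config$betas[2])
        state$weights$critic <- upd$w$critic
        state$adam_c <- upd$state
      }
    }

    ggrads <- NULL
    comps <- c(L_G = 0, Lrec = 0, LrecT = 0, Ldis = 0, adv = 0)
    B <- length(batch)
    for (s in batch) {
      r <- .generator_grads(s$I0, s$I1, s$gt, s$dpm, state$weights, config$net,
                            lw, config$levels,
                            critic_w = if (lw$lambda_adv > 0) state$weights$critic)
      if (lw$lambda_adv > 0) state$critic_evals <- state$critic_evals + 1L
      comps <- comps + c(r$L_G, r$Lrec, r$LrecT, r$Ldis, r$adv) / B
      ggrads <- if (is.null(ggrads)) r$grads else .tree_add(ggrads, r$grads)
    }
    ggrads <- .tree_scale(ggrads, 1 / B)
    if (!all(is.finite(comps)))
      stop("training diverged (non-finite loss) at iteration ", state$iter + it)
    upd <- .adam_update(state$weights[c("stages", "teacher")], ggrads,
                        state$adam_g, config$lr, config$betas[1], config$betas[2])
    state$weights$stages <- upd$w$stages
    state$weights$teacher <- upd$w$teacher
    state$adam_g <- upd$state

    logs[[it]] <- data.frame(iter = state$iter + it,
                             epoch = (state$iter + it - 1L) %/% iters_per_epoch + 1L,
                             L_G = comps["L_G"], Lrec = comps["Lrec"],
                             LrecT = comps["LrecT"], Ldis = comps["Ldis"],
                             adv = comps["adv"], L_D = L_D, gp = gp_mean,
                             critic_evals = state$critic_evals, row.names = NULL)
    new_epoch <- logs[[it]]$epoch
    if (!is.null(config$checkpoint_path) && new_epoch > state$epoch)
      save_checkpoint(state, config$checkpoint_path)
    state$epoch <- new_epoch
  }
  state$iter <- state$iter + n_iters
  state$history <- rbind(state$history, do.call(rbind, logs))
  state$rng <- .Random.seed
  state
}

#' Train the interpolation network
#'
#' Alternating optimization: when `lambda_adv > 0`, each iteration first
#' updates the critic (`critic_steps` times) on ground-truth versus generated
#' planes including the gradient penalty, then updates the generator on its
#' full objective. With `lambda_adv = 0` (direct mode) the critic is never
#' instantiated or evaluated. Batch composition, initialization, augmentation
#' and mixing draws are all deterministic functions of `config$seed`.
#'
#' @param triplets list of `slice_triplet` (see [extract_fixed_triplets()],
#'   [extract_plus_triplets()]).
#' @param config a [train_config()].
#' @return A `ztrain_state`: weights, per-iteration loss `history`
#'   (`L_G, Lrec, LrecT, Ldis, adv, L_D, gp, critic_evals`), optimizer state
#'   and RNG state (resumable with [resume()]).
#' @export
train <- function(triplets, config = train_config()) {
  if (length(triplets) == 0L) stop("no training triplets supplied")
  stopifnot(inherits(config, "train_config"))
  if (!config$net$plus && any(vapply(triplets, function(t) t$z != 0.5, TRUE)))
    stop("fixed-midpoint training requires z = 0.5 triplets; use a plus net_config")
  state <- .init_train_state(config, triplets)
  n_iters <- if (!is.null(config$max_iters)) config$max_iters else
    config$epochs * max(1L, ceiling(length(triplets) / config$batch_size))
  .train_loop(state, triplets, n_iters)
}

#' Save / load / resume training
#'
#' Checkpoints serialize the complete training state (weights, optimizer
#' moments, iteration counters, RNG state, config), so resuming continues
#' exactly where training left off: a run split into two resumed halves
#' reproduces the single run's loss history bit for bit on the same machine.
#'
#' @param state a `ztrain_state`.
#' @param path checkpoint file path.
#' @export
save_checkpoint <- function(state, path) {
  stopifnot(inherits(state, "ztrain_state"))
  saveRDS(state, path)
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) {
  state <- readRDS(path)
  if (!inherits(state, "ztrain_state")) stop("not a training checkpoint: ", path)
  state
}

#' @rdname save_checkpoint
#' @param checkpoint a `ztrain_state` or a path to one.
#' @param triplets training triplets.
#' @param n_iters additional iterations to run.
#' @export
resume <- function(checkpoint, triplets, n_iters) {
  state <- if (is.character(checkpoint)) load_checkpoint(checkpoint) else checkpoint
  stopifnot(inherits(state, "ztrain_state"))
  .check_arch_match(state$weights, state$config)
  if (!is.null(state$rng)) assign(".Random.seed", state$rng, envir = globalenv())
  .train_loop(state, triplets, n_iters)
}
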