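#' Loss weighting
#'
#' Weights balancing the generator objective: reconstruction (student and
#' teacher, unit weight), distillation `lambda_d`, adversarial `lambda_adv`,
#' and the critic's gradient penalty `lambda_gp`. Setting `lambda_adv = 0`
#' reproduces the generator-only (direct) training mode: the critic is never
#' built nor evaluated.
#'
#' @param lambda_d distillation weight (default 0.01).
#' @param lambda_adv adversarial weight (default 0.001; 0 for direct mode).
#' @param lambda_gp gradient-penalty weight (default 10).
#' @return A list of class `loss_weights`.
#' @export
loss_weights <- function(lambda_d = 0.01, lambda_adv = 0.001, lambda_gp = 10) {
  if (lambda_d < 0 || lambda_adv < 0 || lambda_gp < 0)
    stop("loss weights must be non-negative")
  structure(list(lambda_d = lambda_d, lambda_adv = lambda_adv, lambda_gp = lambda_gp),
            class = "loss_weights")
}

# 5-tap binomial kernel as a 1-channel conv weight.
.lap_kernel <- local({
  k1 <- c(1, 4, 6, 4, 1) / 16
  K <- outer(k1, k1)
  array(K, dim = c(5L, 5L, 1L, 1L))
})

.blur_down <- function(x) cpp_conv2d(x, .lap_kernel, 0, 2L, 2L)
.blur_down_adj <- function(g, H, W) cpp_conv2d_bwd_input(g, .lap_kernel, 2L, 2L, H, W)
.pyr_up <- function(x, H, W) cpp_conv2d_bwd_input(x, 4 * .lap_kernel, 2L, 2L, H, W)
.pyr_up_adj <- function(g) cpp_conv2d(g, 4 * .lap_kernel, 0, 2L, 2L)

# Laplacian decomposition of a single plane: levels-1 band-pass components
# plus the residual low-pass top. The map is linear and invertible, so the
# loss below is zero iff the planes are identical.
.lap_decompose <- function(x, levels) {
  g <- list(.as_cube(x))
  for (l in seq_len(levels - 1L)) g[[l + 1L]] <- .blur_down(g[[l]])
  bands <- lapply(seq_len(levels - 1L), function(l)
    g[[l]] - .pyr_up(g[[l + 1L]], dim(g[[l]])[1], dim(g[[l]])[2]))
  list(g = g, bands = c(bands, g[levels]))
}

# Loss and gradient w.r.t. the difference plane d: sum over components of the
# mean absolute value of the component's band of d.
.lap_loss_grad <- function(d, levels, with_grad = TRUE) {
  dec <- .lap_decompose(d, levels)
  loss <- sum(vapply(dec$bands, function(b) mean(abs(b)), 0))
  if (!with_grad) return(list(loss = loss))
  gg <- lapply(dec$bands, function(b) sign(b) / length(b))  # seed per component
  # accumulate gradients back down the Gaussian chain
  for (l in rev(seq_len(levels - 1L))) {
    # band_l = g_l - up(g_{l+1}) contributes +seed_l to g_l and -up^T(seed_l) to g_{l+1}
    gg[[l + 1L]] <- gg[[l + 1L]] - .pyr_up_adj(gg[[l]])
    gg[[l]] <- gg[[l]]
  }
  # propagate g_{l+1} gradients through blur_down into g_l
  for (l in rev(seq_len(levels - 1L))) {
    gg[[l]] <- gg[[l]] + .blur_down_adj(gg[[l + 1L]], dim(dec$g[[l]])[1], dim(dec$g[[l]])[2])
  }
  list(loss = loss, grad = gg[[1L]][, , 1])
}

#' Laplacian-pyramid reconstruction loss
#'
#' Sum over pyramid components (band-pass levels plus the low-pass top) of the
#' mean absolute difference between the two planes' corresponding components.
#' The decomposition is linear and invertible, so the loss is zero iff the
#' planes are identical; with `levels = 1` the single component is the plane
#' itself and the loss reduces to the plain mean absolute difference.
#'
#' @param a,b numeric matrices of identical shape.
#' @param levels number of pyramid components (default 4; 5-tap binomial
#'   kernel, equal component weights).
#' @return A non-negative scalar.
#' @export
laplacian_pyramid_loss <- function(a, b, levels = 4L) {
  if (!all(dim(a) == dim(b))) stop("shape mismatch")
  if (levels < 1L) stop("levels must be >= 1")
  .lap_loss_grad(a - b, as.integer(levels), with_grad = FALSE)$loss
}

#' Distillation loss between student and teacher flows
#'
#' For each student stage, the squared difference between its two flow fields
#' and the teacher's, summed per pixel over the two components and averaged
#' over pixels, then summed over the three stages. The teacher flow is a
#' constant target (no gradient flows into the teacher through this loss).
#'
#' @param student_stages list of 3 stage outputs (each with a `(H,W,4)` `flow`),
#'   as returned in `student_forward()$stages`.
#' @param teacher_stage teacher stage output (with a `(H,W,4)` `flow`).
#' @return A non-negative scalar; zero iff every student stage's flows equal
#'   the teacher's.
#' @export
distillation_loss <- function(student_stages, teacher_stage) {
  if (length(student_stages) != 3L) stop("expected 3 student stages")
  F4 <- teacher_stage$flow
  npix <- prod(dim(F4)[1:2])
  sum(vapply(student_stages, function(s) {
    d <- s$flow - F4
    (sum(d[, , 1:2]^2) + sum(d[, , 3:4]^2)) / npix
  }, 0))
}

#' Generator objective
#'
#' `L_G = Lrec(student, truth) + LrecT(teacher, truth) + lambda_d * Ldis
#'  - lambda_adv * D(student)`. With `lambda_adv = 0` the adversarial term
#' vanishes exactly (direct training mode).
#'
#' @param pred_s student frame.
#' @param pred_t teacher frame (or `NULL`; teacher terms then drop out).
#' @param Izg ground-truth frame.
#' @param student_stages,teacher_stage stage outputs carrying the flows.
#' @param critic a critic object (only used when `lambda_adv > 0`).
#' @param weights a [loss_weights()].
#' @param levels pyramid components for the reconstruction terms.
#' @return A `loss_report` list with `L_G` and its components.
#' @export
generator_loss <- function(pred_s, pred_t, Izg, student_stages = NULL,
                           teacher_stage = NULL, critic = NULL,
                           weights = loss_weights(), levels = 4L) {
  stopifnot(inherits(weights, "loss_weights"))
  lrec <- laplacian_pyramid_loss(pred_s, Izg, levels)
  lrect <- if (is.null(pred_t)) 0 else laplacian_pyramid_loss(pred_t, Izg, levels)
  ldis <- if (is.null(teacher_stage) || is.null(student_stages)) 0 else
    distillation_loss(student_stages, teacher_stage)
  adv <- if (weights$lambda_adv > 0) {
    if (is.null(critic)) stop("lambda_adv > 0 requires a critic")
    critic_score(critic, pred_s)
  } else 0
  total <- lrec + lrect + weights$lambda_d * ldis - weights$lambda_adv * adv
  structure(list(L_G = total, Lrec = lrec, LrecT = lrect, Ldis = ldis, adv = adv,
                 weights = weights),
            class = "loss_report")
}

#' Gradient penalty of the Wasserstein critic
#'
#' Evaluates `lambda_gp * (||grad_x D(x)||_2 - 1)^2` at the convex mixture
#' `x = alpha * real + (1 - alpha) * fake`, the soft 1-Lipschitz constraint of
#' gradient-penalty training. The gradient norm is taken over all pixels of
#' the one mixed plane.
#'
#' @param critic object with an `input_grad(x)` function ([make_critic()], or
#'   an analytic critic in tests).
#' @param real,fake planes of identical shape.
#' @param alpha mixing coefficient in `[0, 1]` (one uniform draw per sample).
#' @param lambda_gp penalty weight.
#' @return A non-negative scalar.
#' @export
gradient_penalty <- function(critic, real, fake, alpha, lambda_gp = 10) {
  if (!all(dim(real) == dim(fake))) stop("shape mismatch")
  if (alpha < 0 || alpha > 1) stop("alpha must lie in [0, 1]")
  x <- alpha * real + (1 - alpha) * fake
  g <- critic$input_grad(x)
  lambda_gp * (sqrt(sum(g^2)) - 1)^2
}

#' Critic objective
#'
#' `L_D = E[D(fake)] - E[D(real)] + lambda_gp * E[(||grad D(x_mix)|| - 1)^2]`,
#' with one uniform mixing draw per sample (caller controls the RNG seed).
#'
#' @param critic a critic object.
#' @param real_batch,fake_batch lists of planes (same length and shape).
#' @param lambda_gp penalty weight.
#' @return A `loss_report` list with `L_D`, the two score means and the mean
#'   penalty.
#' @export
critic_loss <- function(critic, real_batch, fake_batch, lambda_gp = 10) {
  if (length(real_batch) == 0L || length(fake_batch) == 0L) stop("empty batch")
  fs <- vapply(fake_batch, function(x) critic_score(critic, x), 0)
  rs <- vapply(real_batch, function(x) critic_score(critic, x), 0)
  n <- min(length(real_batch), length(fake_batch))
  gp <- vapply(seq_len(n), function(i)
    gradient_penalty(critic, real_batch[[i]], fake_batch[[i]], runif(1), lambda_gp), 0)
  structure(list(L_D = mean(fs) - mean(rs) + mean(gp),
                 fake_score = mean(fs), real_score = mean(rs), penalty = mean(gp)),
            class = "loss_report")
}
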