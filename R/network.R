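#' Network configuration
#'
#' Pins the architecture of the coarse-to-fine intermediate-flow generator and
#' of the Wasserstein critic. The generator has three student stages operating
#' at downsample factors 4, 2, 1; each stage is one stride-2 3x3 convolution,
#' `mid_convs` 3x3 convolutions, and one 4x4 stride-2 transposed convolution
#' emitting 5 channels (two 2-channel flows toward the input planes plus one
#' fusion-mask logit), added as a residual to the previous stage's estimate.
#' The first stage sees the two input planes (plus the constant relative-depth
#' plane in the continuous-z variant); later stages see the planes, both warped
#' candidates and the mask. A teacher stage with the same block structure (but
#' its own weights) additionally receives the ground-truth plane at training
#' time. The critic is a stack of stride-2 4x4 convolutions with LeakyReLU
#' (slope 0.2), no normalization layers, and a linear head.
#'
#' The `"full"` profile reproduces the method's published complexity:
#' 10,601,463 trainable generator (student) parameters (10.6 M) and
#' 11,193,289 critic parameters (11.19 M) at 256x256 input. The `"reduced"`
#' profile is a small configuration for CPU-scale experiments at 64x64.
#'
#' @param profile `"full"` or `"reduced"`.
#' @param plus logical; `TRUE` adds the constant relative-depth (DPM) input
#'   channel to the first stage for continuous-z interpolation.
#' @param input_size lateral input edge in pixels (must be divisible by 8).
#' @return A list of class `net_config`.
#' @export
net_config <- function(profile = c("full", "reduced"), plus = FALSE, input_size = NULL) {
  profile <- match.arg(profile)
  cfg <- if (profile == "full") {
    list(input_size = 256L, scales = c(4L, 2L, 1L), channels = c(328L, 248L, 160L),
         mid_convs = 6L, critic_widths = c(64L, 136L, 256L, 512L, 512L, 512L))
  } else {
    list(input_size = 64L, scales = c(4L, 2L, 1L), channels = c(24L, 16L, 12L),
         mid_convs = 2L, critic_widths = c(16L, 32L, 64L, 64L))
  }
  if (!is.null(input_size)) cfg$input_size <- as.integer(input_size)
  if (cfg$input_size %% 8L != 0L) stop("input_size must be divisible by 8")
  if (cfg$input_size %/% 2L^length(cfg$critic_widths) < 1L)
    stop("critic has too many stride-2 layers for this input size")
  cfg$profile <- profile
  cfg$plus <- isTRUE(plus)
  cfg$leaky_slope <- 0.2
  cfg$teacher_channels <- cfg$channels[length(cfg$channels)]
  structure(cfg, class = "net_config")
}

# Per-stage input channel counts: stage 1 sees (I0, I1[, DPM]); stages 2-3 see
# (I0, I1, warped0, warped1, mask); the teacher additionally sees the ground truth.
.stage_cin <- function(config) {
  c(2L + as.integer(config$plus), 5L, 5L)
}

.init_conv <- function(kh, kw, cin, cout, gain = 2) {
  list(W = array(rnorm(kh * kw * cin * cout, 0, sqrt(gain / (kh * kw * cin))),
                 dim = c(kh, kw, cin, cout)),
       b = numeric(cout))
}

.init_stage <- function(cin, c, mid_convs) {
  list(
    conv_in = .init_conv(3L, 3L, cin, c),
    mid = lapply(seq_len(mid_convs), function(i) .init_conv(3L, 3L, c, c)),
    # transposed conv, stored as the conv (5 -> c) whose adjoint maps c -> 5;
    # zero-initialised so the untrained network predicts zero flow (pure blend)
    out = list(W = array(0, dim = c(4L, 4L, 5L, c)), b = numeric(5L))
  )
}

#' Initialize network weights
#'
#' He-normal initialization for convolutions; every stage's output (transposed)
#' convolution starts at zero so the untrained generator predicts zero flow and
#' a neutral mask, i.e. the plain average of its two input planes.
#'
#' @param config a [net_config()].
#' @param parts which sub-networks to build: any of `"student"`, `"teacher"`,
#'   `"critic"`.
#' @return Nested list of weight arrays.
#' @export
init_weights <- function(config, parts = c("student", "teacher")) {
  stopifnot(inherits(config, "net_config"))
  cin <- .stage_cin(config)
  w <- list()
  if ("student" %in% parts)
    w$stages <- lapply(1:3, function(i) .init_stage(cin[i], config$channels[i], config$mid_convs))
  if ("teacher" %in% parts)
    w$teacher <- .init_stage(6L, config$teacher_channels, config$mid_convs)
  if ("critic" %in% parts) {
    widths <- config$critic_widths
    cins <- c(1L, widths[-length(widths)])
    side <- config$input_size %/% 2L^length(widths)
    w$critic <- list(
      convs = lapply(seq_along(widths), function(i) .init_conv(4L, 4L, cins[i], widths[i])),
      head = list(W = array(rnorm(side * side * widths[length(widths)], 0,
                                  sqrt(1 / (side * side * widths[length(widths)]))),
                            dim = c(side, side, widths[length(widths)])),
                  b = 0)
    )
  }
  w
}

#' Count trainable parameters
#'
#' Instantiates the requested sub-network with the pinned channel configuration
#' and sums all trainable parameters, reported in millions. The full profile
#' counts the student generator at 10.6 M and the critic at 11.19 M.
#'
#' @param config a [net_config()].
#' @param part `"student"` (the inference generator, stages S0-S2), `"teacher"`
#'   (the privileged training stage alone) or `"critic"`.
#' @param millions report millions (default) or the raw integer count.
#' @return Parameter count.
#' @export
count_parameters <- function(config, part = c("student", "critic", "teacher"),
                             millions = TRUE) {
  part <- match.arg(part)
  w <- init_weights(config, parts = part)
  n <- sum(unlist(rapply(w, length, how = "list")))
  if (millions) n / 1e6 else n
}

.lrelu <- function(x, slope) {
  neg <- x < 0
  x[neg] <- x[neg] * slope
  x
}
.lrelu_mask <- function(pre, slope) {
  m <- array(1, dim = dim(pre))
  m[pre < 0] <- slope
  m
}
.sigmoid <- function(x) 1 / (1 + exp(-x))

.as_cube <- function(x) {
  if (is.matrix(x)) array(x, dim = c(dim(x), 1L)) else x
}

.cat_channels <- function(...) {
  parts <- lapply(list(...), .as_cube)
  d <- dim(parts[[1]])[1:2]
  array(unlist(parts), dim = c(d, sum(vapply(parts, function(p) dim(p)[3], 1L))))
}

# Deconv (transposed conv) forward: adjoint of a stride-2 4x4 convolution.
.deconv_fwd <- function(x, layer, Ho, Wo) {
  out <- cpp_conv2d_bwd_input(x, layer$W, 2L, 1L, Ho, Wo)
  sweep(out, 3L, layer$b, "+")
}

# One generator stage: downsample its full-resolution inputs by `scale`,
# run the conv block, and return the residual flow/logit update at full
# resolution (flow values rescaled to full-resolution pixel units).
.stage_fwd <- function(stage, x_full, scale, slope, with_cache = FALSE) {
  H <- dim(x_full)[1]; W <- dim(x_full)[2]
  xs <- if (scale > 1L) cpp_resize_bilinear(x_full, H %/% scale, W %/% scale) else x_full
  pre0 <- cpp_conv2d(xs, stage$conv_in$W, stage$conv_in$b, 2L, 1L)
  a <- .lrelu(pre0, slope)
  acts <- list(a); pres <- list(pre0)
  for (j in seq_along(stage$mid)) {
    pre <- cpp_conv2d(a, stage$mid[[j]]$W, stage$mid[[j]]$b, 1L, 1L)
    a <- .lrelu(pre, slope)
    pres[[j + 1L]] <- pre; acts[[j + 1L]] <- a
  }
  out5 <- .deconv_fwd(a, stage$out, dim(xs)[1], dim(xs)[2])
  delta <- if (scale > 1L) cpp_resize_bilinear(out5, H, W) else out5
  res <- list(dflow = delta[, , 1:4, drop = FALSE] * scale, dlogit = delta[, , 5])
  if (with_cache)
    res$cache <- list(xs = xs, pres = pres, acts = acts, out5_dim = dim(out5),
                      scale = scale, full_dim = c(H, W))
  res
}

# Backward through one stage. gflow (H,W,4) and glogit (H,W) are gradients
# w.r.t. this stage's *residual* contribution at full resolution. Returns the
# weight gradients and the gradient w.r.t. the stage's full-resolution input.
.stage_bwd <- function(stage, cache, gflow, glogit, slope) {
  scale <- cache$scale
  gdelta <- .cat_channels(gflow * scale, glogit)
  gout5 <- if (scale > 1L)
    cpp_resize_bilinear_adj(gdelta, cache$out5_dim[1], cache$out5_dim[2]) else gdelta
  k <- length(stage$mid)
  ak <- cache$acts[[k + 1L]]
  gW_out <- cpp_conv2d_bwd_weight(gout5, ak, 4L, 4L, 2L, 1L)$W
  gb_out <- apply(gout5, 3L, sum)
  ga <- cpp_conv2d(gout5, stage$out$W, numeric(dim(ak)[3]), 2L, 1L)
  gmid <- vector("list", k)
  for (j in rev(seq_len(k))) {
    gpre <- ga * .lrelu_mask(cache$pres[[j + 1L]], slope)
    gw <- cpp_conv2d_bwd_weight(cache$acts[[j]], gpre, 3L, 3L, 1L, 1L)
    gmid[[j]] <- list(W = gw$W, b = gw$b)
    ga <- cpp_conv2d_bwd_input(gpre, stage$mid[[j]]$W, 1L, 1L,
                               dim(cache$acts[[j]])[1], dim(cache$acts[[j]])[2])
  }
  gpre0 <- ga * .lrelu_mask(cache$pres[[1L]], slope)
  gw_in <- cpp_conv2d_bwd_weight(cache$xs, gpre0, 3L, 3L, 2L, 1L)
  gxs <- cpp_conv2d_bwd_input(gpre0, stage$conv_in$W, 2L, 1L,
                              dim(cache$xs)[1], dim(cache$xs)[2])
  gx_full <- if (scale > 1L)
    cpp_resize_bilinear_adj(gxs, cache$full_dim[1], cache$full_dim[2]) else gxs
  list(grads = list(conv_in = list(W = gw_in$W, b = gw_in$b), mid = gmid,
                    out = list(W = gW_out, b = gb_out)),
       gx = gx_full)
}

#' Backward warping
#'
#' Resamples `image` with border-clamped bilinear interpolation at
#' `(x + dx, y + dy)` for every output pixel: `output(p) = image(p + flow(p))`.
#' Zero flow is the exact identity.
#'
#' @param image numeric matrix.
#' @param flow numeric array `(H, W, 2)`; channel 1 is the column offset `dx`,
#'   channel 2 the row offset `dy`, in pixels.
#' @return The warped matrix.
#' @examples
#' img <- matrix(c(0, 10), 1)
#' backward_warp(img, array(c(0.5, 0), c(1, 2, 2)) * c(1, 1, 0, 0))
#' @export
backward_warp <- function(image, flow) {
  if (!is.matrix(image)) stop("image must be a matrix")
  if (length(dim(flow)) != 3L || !all(dim(flow) == c(dim(image), 2L)))
    stop("flow must be (H, W, 2) matching the image")
  cpp_warp(image, flow)
}

#' Mask fusion of two candidate frames
#'
#' Elementwise convex blend `M * frame0 + (1 - M) * frame1`. The output is
#' everywhere bounded by the two inputs.
#'
#' @param M fusion mask in `[0, 1]`, same shape as the frames.
#' @param frame0,frame1 numeric matrices.
#' @return The fused matrix.
#' @export
fuse <- function(M, frame0, frame1) {
  if (!all(dim(M) == dim(frame0)) || !all(dim(M) == dim(frame1)))
    stop("fuse: shape mismatch")
  if (any(M < 0) || any(M > 1)) stop("fuse: mask values must lie in [0, 1]")
  M * frame0 + (1 - M) * frame1
}

#' Student generator forward pass
#'
#' Runs the three coarse-to-fine stages. Stage 1 consumes the two input planes
#' (plus the constant relative-depth plane in the continuous-z variant); each
#' later stage consumes the planes, the current warped candidates and the
#' fusion mask, and refines the flow/mask residually. The synthesized frame is
#' the mask fusion of the two stage-3 warped candidates.
#'
#' @param I0,I1 input planes (matrices on the network scale, `[0, 1]`).
#' @param config a [net_config()].
#' @param weights from [init_weights()] (or a trained model).
#' @param dpm a [make_dpm()] plane; required iff `config$plus`.
#' @param with_cache keep intermediate activations (training only).
#' @return A `generator_output` list: `frame`, per-stage `stages` (each with
#'   `flow` `(H,W,4)`, `mask`, `logit`), `warped` candidates, and `cache`.
#' @export
student_forward <- function(I0, I1, config, weights, dpm = NULL, with_cache = FALSE) {
  stopifnot(inherits(config, "net_config"))
  if (!all(dim(I0) == dim(I1))) stop("input planes differ in shape")
  if (config$plus && is.null(dpm)) stop("continuous-z variant requires a dpm plane")
  if (!config$plus && !is.null(dpm)) stop("fixed-midpoint variant takes no dpm plane")
  H <- dim(I0)[1]; W <- dim(I0)[2]
  flow <- array(0, c(H, W, 4L)); logit <- matrix(0, H, W)
  stages <- list(); warped <- list(); caches <- list(); xin <- list()
  for (i in 1:3) {
    x <- if (i == 1L) {
      if (config$plus) .cat_channels(I0, I1, unclass(dpm)) else .cat_channels(I0, I1)
    } else {
      s <- stages[[i - 1L]]
      .cat_channels(I0, I1, warped[[i - 1L]]$w0, warped[[i - 1L]]$w1, s$mask)
    }
    st <- .stage_fwd(weights$stages[[i]], x, config$scales[i], config$leaky_slope,
                     with_cache = with_cache)
    flow <- flow + st$dflow
    logit <- logit + st$dlogit
    M <- .sigmoid(logit)
    w0 <- cpp_warp(I0, flow[, , 1:2, drop = FALSE])
    w1 <- cpp_warp(I1, flow[, , 3:4, drop = FALSE])
    stages[[i]] <- list(flow = flow, mask = M, logit = logit, stage = i)
    warped[[i]] <- list(w0 = w0, w1 = w1)
    if (with_cache) { caches[[i]] <- st$cache; xin[[i]] <- x }
  }
  M3 <- stages[[3]]$mask
  out <- list(frame = fuse(M3, warped[[3]]$w0, warped[[3]]$w1),
              stages = stages, warped = warped)
  if (with_cache) out$cache <- list(stage = caches, x = xin, I0 = I0, I1 = I1)
  structure(out, class = "generator_output")
}

#' Teacher forward pass
#'
#' The privileged fourth stage used only at training time. It reuses the
#' student's stage-3 activations (warped candidates and mask) and additionally
#' receives the ground-truth plane, emitting refined flows, a refined mask and
#' the teacher frame. It shares the student stages' architecture but has its
#' own weights.
#'
#' @param I0,I1 input planes on the network scale.
#' @param student_output a `generator_output` from [student_forward()].
#' @param Izg ground-truth intermediate plane.
#' @inheritParams student_forward
#' @return The `generator_output` extended with `teacher_frame`,
#'   `teacher_stage` and `teacher_warped`.
#' @export
teacher_forward <- function(I0, I1, student_output, Izg, config, weights,
                            with_cache = FALSE) {
  stopifnot(inherits(student_output, "generator_output"))
  if (is.null(weights$teacher)) stop("weights contain no teacher stage")
  if (!all(dim(Izg) == dim(I0))) stop("ground-truth plane shape mismatch")
  s3 <- student_output$stages[[3]]
  w3 <- student_output$warped[[3]]
  x <- .cat_channels(I0, I1, w3$w0, w3$w1, s3$mask, Izg)
  st <- .stage_fwd(weights$teacher, x, 1L, config$leaky_slope, with_cache = with_cache)
  flow4 <- s3$flow + st$dflow
  logit4 <- s3$logit + st$dlogit
  M4 <- .sigmoid(logit4)
  w0 <- cpp_warp(I0, flow4[, , 1:2, drop = FALSE])
  w1 <- cpp_warp(I1, flow4[, , 3:4, drop = FALSE])
  student_output$teacher_stage <- list(flow = flow4, mask = M4, logit = logit4, stage = 4L)
  student_output$teacher_warped <- list(w0 = w0, w1 = w1)
  student_output$teacher_frame <- fuse(M4, w0, w1)
  if (with_cache) {
    student_output$cache$teacher <- st$cache
    student_output$cache$teacher_x <- x
  }
  student_output
}

#' Construct a critic (Wasserstein discriminator)
#'
#' Wraps critic weights as an object exposing `score(x)` (one unbounded real
#' number per plane) and `input_grad(x)` (the gradient of the score with
#' respect to the input plane, needed by the gradient penalty and by the
#' generator's adversarial term).
#'
#' @param weights weight list containing `$critic` (see [init_weights()]).
#' @param config a [net_config()].
#' @return An object of class `zcritic`.
#' @export
make_critic <- function(weights, config) {
  if (is.null(weights$critic)) stop("weights contain no critic")
  structure(list(weights = weights$critic, config = config,
                 score = function(x) .critic_fwd(x, weights$critic, config)$score,
                 input_grad = function(x) {
                   cache <- .critic_fwd(x, weights$critic, config)
                   .critic_input_grad(cache, weights$critic, config)$g
                 }),
            class = "zcritic")
}

#' Score a plane with the critic
#'
#' @param critic a `zcritic` (from [make_critic()]), or any list with a
#'   `score` function (tests use analytic critics).
#' @param image numeric matrix on the network scale.
#' @return A single unbounded real score.
#' @export
critic_score <- function(critic, image) {
  critic$score(image)
}

.critic_fwd <- function(x, cw, config) {
  a <- .as_cube(x)
  acts <- list(a); pres <- list()
  for (i in seq_along(cw$convs)) {
    pre <- cpp_conv2d(a, cw$convs[[i]]$W, cw$convs[[i]]$b, 2L, 1L)
    a <- .lrelu(pre, config$leaky_slope)
    pres[[i]] <- pre; acts[[i + 1L]] <- a
  }
  list(score = sum(cw$head$W * a) + cw$head$b, acts = acts, pres = pres)
}

# Gradient of the critic score w.r.t. its input plane, with the intermediate
# cotangents cached (u_hat per layer) for the penalty's double backward.
.critic_input_grad <- function(cache, cw, config) {
  u <- cw$head$W
  uhat <- vector("list", length(cw$convs))
  for (i in rev(seq_along(cw$convs))) {
    uhat[[i]] <- u * .lrelu_mask(cache$pres[[i]], config$leaky_slope)
    prev <- cache$acts[[i]]
    u <- cpp_conv2d_bwd_input(uhat[[i]], cw$convs[[i]]$W, 2L, 1L,
                              dim(prev)[1], dim(prev)[2])
  }
  list(g = u[, , 1], uhat = uhat)
}

# Standard weight gradients of the critic score (seed dscore = 1).
.critic_score_wgrads <- function(cache, cw, config, seed = 1) {
  L <- length(cw$convs)
  grads <- list(convs = vector("list", L),
                head = list(W = cache$acts[[L + 1L]] * seed, b = seed))
  ga <- cw$head$W * seed
  for (i in rev(seq_len(L))) {
    gpre <- ga * .lrelu_mask(cache$pres[[i]], config$leaky_slope)
    gw <- cpp_conv2d_bwd_weight(cache$acts[[i]], gpre, 4L, 4L, 2L, 1L)
    grads$convs[[i]] <- list(W = gw$W, b = gw$b)
    if (i > 1L)
      ga <- cpp_conv2d_bwd_input(gpre, cw$convs[[i]]$W, 2L, 1L,
                                 dim(cache$acts[[i]])[1], dim(cache$acts[[i]])[2])
  }
  grads
}

# Weight gradients of the gradient penalty lambda*(||g|| - 1)^2 at one input.
# The input gradient g of a piecewise-linear critic is multilinear in the
# weights (each conv appears once; LeakyReLU masks are locally constant), so
# the derivative is obtained by propagating the penalty seed forward through
# the adjoint of the backward chain and pairing it with the cached cotangents.
.critic_gp_wgrads <- function(x, cw, config, lambda_gp) {
  cache <- .critic_fwd(x, cw, config)
  ig <- .critic_input_grad(cache, cw, config)
  gnorm <- sqrt(sum(ig$g^2))
  penalty <- lambda_gp * (gnorm - 1)^2
  seed_scale <- if (gnorm > 0) 2 * lambda_gp * (gnorm - 1) / gnorm else 0
  s <- .as_cube(ig$g * seed_scale)
  L <- length(cw$convs)
  grads <- list(convs = vector("list", L), head = list(W = NULL, b = 0))
  for (i in seq_len(L)) {
    gw <- cpp_conv2d_bwd_weight(s, uhat_i <- ig$uhat[[i]], 4L, 4L, 2L, 1L)
    grads$convs[[i]] <- list(W = gw$W, b = numeric(length(cw$convs[[i]]$b)))
    s <- cpp_conv2d(s, cw$convs[[i]]$W, numeric(dim(uhat_i)[3]), 2L, 1L) *
      .lrelu_mask(cache$pres[[i]], config$leaky_slope)
  }
  grads$head$W <- s
  list(penalty = penalty, grads = grads, gnorm = gnorm)
}
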