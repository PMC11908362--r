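# Deterministic integer test images, reproducible bit-exactly across languages
# (the frozen SSIM reference values were computed on exactly these patterns).
img_lattice <- function(n) {
  i <- matrix(1:n, n, n); j <- t(i)
  (7 * i + 13 * j + 5 * ((i * j) %% 11)) %% 256
}
img_quadratic <- function(n) {
  i <- matrix(1:n, n, n); j <- t(i)
  (3 * i * i + 11 * j + ((i + j) %% 17) * 9) %% 256
}
img_perturbed <- function(n) {
  a <- img_lattice(n)
  idx <- matrix(0:(n - 1), n, n)
  pmin(pmax(a + (idx * t(idx)) %% 7 - 3, 0), 255)
}

# small random stack with integer 8-bit values
random_stack <- function(ny = 8, nx = 8, nz = 3, seed = 1, spacing = NULL) {
  set.seed(seed)
  zstack(array(as.double(sample(0:255, ny * nx * nz, replace = TRUE)), c(ny, nx, nz)),
         spacing = spacing)
}

# tiny network fixtures for CPU-fast forward/backward tests
tiny_config <- function(plus = FALSE, input_size = 16L) {
  net_config("reduced", plus = plus, input_size = input_size)
}
tiny_weights <- function(cfg, parts = c("student", "teacher"), seed = 1,
                         randomize_out = FALSE) {
  set.seed(seed)
  w <- init_weights(cfg, parts)
  if (randomize_out)
    w <- rapply(w, function(x) {
      if (all(x == 0)) x[] <- rnorm(length(x), 0, 0.1)
      x
    }, how = "replace")
  w
}
zero_weights <- function(cfg, parts = c("student", "teacher")) {
  rapply(init_weights(cfg, parts), function(x) x * 0, how = "replace")
}

# analytic linear critic D(x) = c * sum(x): exactly (c*sqrt(npix))-Lipschitz
linear_critic <- function(c0 = 1) {
  list(score = function(x) c0 * sum(x),
       input_grad = function(x) matrix(c0, nrow(x), ncol(x)))
}

# a model wrapper around explicit weights for the inference API
as_model <- function(weights, cfg) list(weights = weights, net = cfg)

# shared toy training set (built once per test run)
toy_triplets <- local({
  cache <- NULL
  function(n_stacks = 6, size = 32, n_slices = 5, seed = 11) {
    if (is.null(cache)) {
      stacks <- lapply(seq_len(n_stacks), function(i) {
        ph <- make_phantom(phantom_spec("shell", size = size, n_slices = n_slices,
                                        radius = 0.25 * size, drift = c(0.6, -0.4),
                                        noise_sd = 2, seed = seed + i))
        ph$stack
      })
      cache <<- unlist(lapply(seq_along(stacks), function(i)
        extract_fixed_triplets(stacks[[i]], stack_id = as.character(i))),
        recursive = FALSE)
    }
    cache
  }
})
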