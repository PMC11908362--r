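test_that("fixed-midpoint triplets enumerate consecutive triples", {
  s <- random_stack(8, 8, 3, seed = 1)
  tr <- extract_fixed_triplets(s)
  expect_length(tr, 1L)
  expect_equal(tr[[1]]$source$indices, c(1L, 2L, 3L))
  expect_equal(tr[[1]]$z, 0.5)
  expect_identical(tr[[1]]$Izg, get_plane(s, 2))

  expect_length(extract_fixed_triplets(random_stack(4, 4, 2)), 0L)
  expect_length(extract_fixed_triplets(random_stack(4, 4, 36, seed = 2)), 34L)
})

test_that("windowed triplet enumeration matches a brute-force oracle", {
  # brute force: all (t, n1, n2, n3) with t-window+1 <= n1 < n2 < n3 <= t
  brute <- function(n, window) {
    out <- NULL
    for (t in seq_len(n)) {
      if (t < 3) next
      if (n > window && t < window) next
      lo <- max(1L, t - window + 1L)
      for (n1 in lo:(t - 2)) for (n2 in (n1 + 1):(t - 1)) for (n3 in (n2 + 1):t)
        out <- rbind(out, c(n1, n2, n3))
    }
    unique(out)
  }
  for (n in c(3L, 6L, 9L, 12L)) {
    got <- plus_triplet_indices(n, 8L)
    want <- brute(n, 8L)
    want <- want[order(want[, 1], want[, 2], want[, 3]), , drop = FALSE]
    expect_equal(unname(unclass(got)), unname(want), info = paste("n =", n))
  }
  # window spanning the whole stack reduces to all choose(n, 3) triples
  expect_equal(nrow(plus_triplet_indices(9L, 9L)), choose(9, 3))
  expect_equal(nrow(plus_triplet_indices(9L, 8L)),
               nrow(unique(rbind(t(utils::combn(1:8, 3)), t(utils::combn(2:9, 3))))))
})

test_that("triplet relative positions follow the index arithmetic", {
  s <- random_stack(4, 4, 9, seed = 3)
  tr <- extract_plus_triplets(s, window = 9L)
  idx <- t(vapply(tr, function(t) t$source$indices, integer(3)))
  z <- vapply(tr, function(t) t$z, 0)
  expect_true(all(idx[, 1] < idx[, 2] & idx[, 2] < idx[, 3]))
  expect_true(all(z > 0 & z < 1))
  expect_equal(z, (idx[, 2] - idx[, 1]) / (idx[, 3] - idx[, 1]))
  # a (1, 3, 9) triple carries z = 0.25
  k <- which(idx[, 1] == 1 & idx[, 2] == 3 & idx[, 3] == 9)
  expect_equal(tr[[k]]$z, 0.25)
  # N = 3: single triplet at the midpoint
  tr3 <- extract_plus_triplets(random_stack(4, 4, 3), window = 8L)
  expect_length(tr3, 1L)
  expect_equal(tr3[[1]]$z, 0.5)
})

test_that("constant relative-depth planes are validated and constant", {
  expect_identical(unclass(make_dpm(0, c(4, 4)))[1:16], rep(0, 16))
  expect_true(all(make_dpm(1, c(3, 5)) == 1))
  d <- make_dpm(0.25, c(16, 16))
  expect_equal(dim(d), c(16L, 16L))
  expect_true(all(d == 0.25))
  expect_error(make_dpm(1.2, c(4, 4)), "\\[0, 1\\]")
  expect_error(make_dpm(-0.1, c(4, 4)), "\\[0, 1\\]")
})

test_that("augmentation applies one shared transform and preserves z", {
  s <- random_stack(8, 8, 3, seed = 4)
  tr <- extract_fixed_triplets(s)[[1]]
  expect_identical(augment_triplet(tr, augment_spec_identity()), tr)

  # forced 180 degrees is an involution on every plane
  spec180 <- augment_spec(contrast = c(1, 1), brightness = c(0, 0),
                          rotations = 180L, p_flip = 0)
  once <- augment_triplet(tr, spec180)
  expect_false(identical(once$I0, tr$I0))
  twice <- augment_triplet(once, spec180)
  expect_identical(twice, tr)

  set.seed(99); a <- augment_triplet(tr, augment_spec())
  set.seed(99); b <- augment_triplet(tr, augment_spec())
  expect_identical(a, b)
  expect_equal(a$z, tr$z)
  expect_true(all(a$I0 >= 0 & a$I0 <= 255))
  expect_equal(dim(a$Izg), dim(tr$Izg))
})

test_that("triplet cache round-trips through its manifest", {
  s <- random_stack(8, 8, 5, seed = 5)
  tr <- extract_fixed_triplets(s, stack_id = "stackA")
  dir <- file.path(tempdir(), "tripcache")
  write_triplet_cache(tr, dir)
  back <- read_triplet_cache(dir)
  expect_length(back, length(tr))
  for (i in seq_along(tr)) {
    expect_identical(back[[i]]$I0, tr[[i]]$I0)
    expect_identical(back[[i]]$Izg, tr[[i]]$Izg)
    expect_equal(back[[i]]$z, tr[[i]]$z)
    expect_equal(back[[i]]$source$indices, tr[[i]]$source$indices)
  }
})
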