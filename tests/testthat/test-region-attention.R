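# Region decomposition, shared encoder contracts, gated attention, the
# attended summary, and the entropy regularizer.

test_that("decompose_regions equals the per-voxel indicator oracle", {
  set.seed(2)
  vol <- array(rnorm(6^3), dim = c(6, 6, 6))
  mask <- array(rbinom(6^3, 1, 0.5), dim = c(6, 6, 6))
  out <- decompose_regions(vol, list(mask))[[1]]
  oracle <- array(0, dim = dim(vol))
  for (i in 1:6) for (j in 1:6) for (k in 1:6)
    oracle[i, j, k] <- if (mask[i, j, k] == 1) vol[i, j, k] else 0
  expect_equal(out, oracle)
  # indicator algebra and the empty mask
  ones <- array(1, dim = c(6, 6, 6))
  expect_equal(decompose_regions(ones, list(mask))[[1]], mask + 0)
  expect_equal(decompose_regions(vol, list(ones * 0))[[1]], ones * 0)
  expect_error(decompose_regions(vol, list(array(1, dim = c(4, 4, 4)))),
               "mask 1")
})

test_that("the shared encoder is deterministic, weight-shared, and shape-correct", {
  cfg <- encoder_config(channels = 4L, blocks = 1L)
  par <- init_encoder_params(cfg, seed = 3L)
  v <- array(rnorm(16^3), dim = c(16, 16, 16))
  f1 <- encode_region(v, par, cfg)
  f2 <- encode_region(v, par, cfg)
  expect_identical(f1, f2) # same params applied to identical subvolumes
  expect_equal(dim(f1), c(8L, 8L, 8L, 4L))
  expect_error(encode_region(array(0, dim = c(2, 2, 2)), par, cfg),
               "receptive-field")
})

test_that("a bias-free encoder maps the zero volume to zero features", {
  cfg <- encoder_config(channels = 4L, blocks = 1L, bias = FALSE)
  par <- init_encoder_params(cfg, seed = 3L)
  f <- encode_region(array(0, dim = c(16, 16, 16)), par, cfg)
  expect_equal(max(abs(f)), 0)
})

test_that("gated attention matches the sigmoid-tanh gate formula", {
  set.seed(11)
  C <- 6
  par <- init_attention_params(C, seed = 2L)
  pooled <- lapply(1:4, function(i) rnorm(C))
  a <- unlist(gated_attention(pooled, par))
  oracle <- vapply(pooled, function(x)
    1 / (1 + exp(-sum(par$w * tanh(par$Wg %*% x)))), numeric(1))
  expect_close(a, oracle, 1e-6)
  expect_true(all(a >= 0 & a <= 1))
  # zero projection gives sigma(0) = 0.5; identical descriptors identical weights
  zpar <- list(Wg = matrix(0, C, C), w = rnorm(C))
  expect_equal(unlist(gated_attention(pooled, zpar)), rep(0.5, 4))
  same <- gated_attention(list(pooled[[1]], pooled[[1]]), par)
  expect_equal(same[[1]], same[[2]])
})

test_that("attended summary is the weighted sum, with a normalized variant", {
  pooled <- list(c(1, 0), c(0, 1))
  expect_equal(attended_summary(pooled, c(1, 0)), c(1, 0))
  expect_equal(attended_summary(pooled, c(0.5, 0.5)), c(0.5, 0.5))
  # permutation of regions and weights together leaves r unchanged
  set.seed(4)
  pl <- lapply(1:5, function(i) rnorm(3))
  w <- runif(5)
  expect_equal(attended_summary(pl, w), attended_summary(rev(pl), rev(w)))
  # normalization divides by the weight total
  expect_equal(attended_summary(pooled, c(2, 2), normalize = TRUE), c(0.5, 0.5))
  expect_error(attended_summary(pooled, c(0, 0), normalize = TRUE),
               "all-zero")
  # bound: |r| <= max |h| * sum(alpha)
  expect_lte(max(abs(attended_summary(pl, w))),
             max(vapply(pl, function(x) max(abs(x)), numeric(1))) * sum(w) + 1e-12)
})

test_that("entropy regularizer follows both sign conventions", {
  onehot <- c(1, 0, 0, 0)
  expect_equal(entropy_regularizer(onehot), 0)
  expect_equal(entropy_regularizer(onehot, as_printed = TRUE), 0)
  u5 <- rep(1 / 5, 5)
  expect_equal(entropy_regularizer(u5), log(5), tolerance = 1e-12)
  expect_equal(entropy_regularizer(u5, as_printed = TRUE), -log(5), tolerance = 1e-12)
  expect_error(entropy_regularizer(c(-1, 2)), "nonnegative")
  expect_error(entropy_regularizer(c(0, 0)), "not all be zero")
  # H maximal at uniform, zero only at one-hot, vs brute-force oracle
  set.seed(9)
  for (i in 1:100) {
    K <- sample(2:6, 1)
    w <- runif(K)
    p <- w / sum(w)
    oracle <- -sum(ifelse(p > 0, p * log(p), 0))
    expect_close(entropy_regularizer(w), oracle, 1e-10)
    expect_equal(entropy_regularizer(w), -entropy_regularizer(w, as_printed = TRUE))
    expect_lte(entropy_regularizer(w), log(K) + 1e-12)
    if (oracle < 1e-12) expect_equal(sort(p, decreasing = TRUE)[1], 1)
  }
})

test_that("decompose/encode/pool pipeline commutes with region permutation", {
  st <- FIX_COHORT[[1]]
  cfg <- encoder_config(channels = 4L, blocks = 1L)
  par <- init_encoder_params(cfg, seed = 3L)
  apar <- init_attention_params(4L, seed = 2L)
  pipe <- function(masks) {
    subs <- decompose_regions(st$volume, masks)
    h <- lapply(subs, function(s) lobenet:::t_gap(encode_region(s, par, cfg)))
    unlist(gated_attention(h, apar))
  }
  perm <- c(3, 1, 5, 2, 4)
  expect_equal(pipe(st$masks)[perm], unname(pipe(st$masks[perm])))
})

test_that("attention dropout is identity in evaluation and rescales in training", {
  w <- as.list(rep(0.5, 100))
  expect_identical(attention_dropout(w, rate = 0.5, train = FALSE), w)
  set.seed(8)
  out <- unlist(attention_dropout(w, rate = 0.5, train = TRUE))
  expect_true(all(out %in% c(0, 1)))
  expect_gt(mean(out), 0.3) # survivors rescaled by 1/(1-rate)
})
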