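# Hierarchical consistency, center loss, linear MMD, mask-guided TV, and
# severity regression: hand-computed cases, brute-force oracles, and
# exact-zero witnesses.

test_that("hierarchical consistency penalizes the residual to the weighted sum", {
  z <- c(1, 0)
  expect_equal(hierarchical_consistency(z, list(list(c(0, 0))), alpha = 1), 1)
  zk <- list(c(1, 0), c(0, 1))
  a <- c(0.3, 0.7)
  comb <- 0.3 * zk[[1]] + 0.7 * zk[[2]]
  expect_equal(hierarchical_consistency(comb, list(zk), a), 0)
  # isometry: joint rotation leaves the loss unchanged
  set.seed(2)
  Q <- qr.Q(qr(matrix(rnorm(4), 2)))
  zr <- as.numeric(Q %*% z)
  zkr <- lapply(zk, function(v) as.numeric(Q %*% v))
  expect_equal(hierarchical_consistency(z, list(zk), a),
               hierarchical_consistency(zr, list(zkr), a), tolerance = 1e-12)
  expect_error(hierarchical_consistency(c(1, 0, 0), list(zk), a), "dims disagree")
})

test_that("simplex weights stay on the simplex for any logits", {
  set.seed(3)
  for (i in 1:50) {
    a <- simplex_weights(rnorm(sample(2:8, 1), sd = 5))
    expect_true(all(a >= 0))
    expect_equal(sum(a), 1, tolerance = 1e-12)
  }
})

test_that("center loss matches hand values and scales quadratically", {
  cent <- list(`0` = c(0, 0), `1` = c(1, 1))
  expect_equal(center_loss(rbind(c(1, 0)), 0, cent), 1)
  expect_equal(center_loss(rbind(c(0, 0), c(1, 1)), c(0, 1), cent), 0)
  z <- rbind(c(2, 0))
  expect_equal(center_loss(z, 0, cent), 4) # doubling distance quadruples
  expect_error(center_loss(z, 5, cent), "no centroid")
  # EMA update moves centroids toward class means
  up <- update_centroids(cent, rbind(c(2, 2)), 1, rate = 0.5)
  expect_equal(up[["1"]], c(1.5, 1.5))
})

test_that("linear MMD equals the squared distance of batch means", {
  expect_equal(mmd_linear(rbind(0), rbind(1)), 1)
  set.seed(4)
  A <- rmat(5, 3); B <- rmat(7, 3)
  oracle <- sum((colMeans(A) - colMeans(B))^2)
  expect_close(mmd_linear(A, B), oracle, 1e-12)
  expect_equal(mmd_linear(A, A), 0)
  expect_equal(mmd_linear(A[sample(5), ], B), mmd_linear(A, B))
  expect_error(mmd_linear(A[0, , drop = FALSE], B), "nonempty")
})

test_that("mask TV counts only in-mask forward differences", {
  m <- array(0, dim = c(3, 1, 1)); m[1:2, 1, 1] <- 1
  f <- array(0, dim = c(3, 1, 1)); f[2, 1, 1] <- 1
  expect_equal(mask_tv(list(f), list(m)), 1)
  # constant map -> 0; single-voxel masks -> 0
  expect_equal(mask_tv(list(array(5, dim = c(4, 4, 4))),
                       list(array(1, dim = c(4, 4, 4)))), 0)
  m1 <- array(0, dim = c(4, 4, 4)); m1[2, 2, 2] <- 1
  expect_equal(mask_tv(list(array(rnorm(64), dim = c(4, 4, 4))), list(m1)), 0)
  # brute-force oracle on a random map with a channel axis
  set.seed(6)
  fm <- array(rnorm(3 * 3 * 3 * 2), dim = c(3, 3, 3, 2))
  mk <- array(rbinom(27, 1, 0.6), dim = c(3, 3, 3))
  oracle <- 0
  for (c in 1:2) for (i in 1:3) for (j in 1:3) for (k in 1:3) {
    if (i < 3 && mk[i, j, k] && mk[i + 1, j, k])
      oracle <- oracle + abs(fm[i + 1, j, k, c] - fm[i, j, k, c])
    if (j < 3 && mk[i, j, k] && mk[i, j + 1, k])
      oracle <- oracle + abs(fm[i, j + 1, k, c] - fm[i, j, k, c])
    if (k < 3 && mk[i, j, k] && mk[i, j, k + 1])
      oracle <- oracle + abs(fm[i, j, k + 1, c] - fm[i, j, k, c])
  }
  expect_close(mask_tv(list(fm), list(mk)), oracle, 1e-10)
})

test_that("severity regression loss is the symmetric MSE", {
  expect_equal(patho_regression_loss(2, 1), 1)
  expect_equal(patho_regression_loss(1, 2), 1)
  expect_equal(patho_regression_loss(c(1, 2), c(1, 2)), 0)
  psi <- list(w = c(0.5, -1), b = 0.25)
  z <- c(2, 1)
  expect_equal(severity_head(z, psi), 0.5 * 2 - 1 + 0.25)
})

test_that("every structural prior admits an exact zero and is nonnegative", {
  set.seed(7)
  z <- rmat(4, 3)
  expect_gte(hierarchical_consistency(z, lapply(1:4, function(i) list(rvec(3), rvec(3))),
                                      c(0.5, 0.5)), 0)
  expect_gte(mmd_linear(rmat(3, 2), rmat(3, 2)), 0)
  expect_gte(patho_regression_loss(rvec(4), rvec(4)), 0)
  expect_gte(mask_tv(list(array(rnorm(27), dim = c(3, 3, 3))),
                     list(array(1, dim = c(3, 3, 3)))), 0)
})
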