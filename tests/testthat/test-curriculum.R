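# Stage-1 objectives: masked reconstruction under both mask conventions,
# the contrastive loss against closed forms and a brute-force oracle, the
# weighted auxiliary combination, momentum updates, and block masks.

test_that("masked reconstruction averages over occluded voxels only", {
  I <- array(1, dim = c(2, 2, 2))
  Ih <- array(0, dim = c(2, 2, 2))
  M <- array(0, dim = c(2, 2, 2)); M[1, 1, 1] <- 1
  expect_equal(masked_recon_loss(I, Ih, M), 1) # single occluded voxel, (1-0)^2
  Ih2 <- I; Ih2[2, 2, 2] <- 99 # error outside the occlusion is ignored
  expect_equal(masked_recon_loss(I, Ih2, M), 0)
  # literal convention: || recon - original * mask ||^2 over all voxels
  expect_equal(masked_recon_loss(I, Ih, M, as_printed = TRUE), 1)
  expect_equal(masked_recon_loss(I, I, M, as_printed = TRUE), 7) # unmasked ones remain
  expect_error(masked_recon_loss(I, Ih, array(0, dim = c(2, 2, 2))), "nothing")
  # growing the occluded set only changes the mean through new voxels
  set.seed(1)
  I <- array(rnorm(64), dim = c(4, 4, 4))
  Ih <- array(rnorm(64), dim = c(4, 4, 4))
  M1 <- array(0, dim = c(4, 4, 4)); M1[1:2, , ] <- 1
  M2 <- M1; M2[3, , ] <- 1
  d2 <- (Ih - I)^2
  l1 <- masked_recon_loss(I, Ih, M1)
  l2 <- masked_recon_loss(I, Ih, M2)
  expect_equal(l2, (l1 * sum(M1) + sum(d2[M2 == 1 & M1 == 0])) / sum(M2))
})

test_that("contrastive loss reaches its closed forms", {
  v <- rnorm(6)
  same <- lapply(1:3, function(i) v)
  expect_equal(ad_value(simclr_loss(same, same, tau = 0.5)), log(2),
               tolerance = 1e-12)
  # aligned positives, orthogonal negatives: -1/tau + log(N-1)
  e <- diag(3)
  z <- lapply(1:3, function(i) e[i, ])
  expect_equal(ad_value(simclr_loss(z, z, tau = 0.5)), -2 + log(2),
               tolerance = 1e-12)
  # scale invariance of cosine similarity
  z2 <- lapply(z, function(x) 7.3 * x)
  expect_equal(ad_value(simclr_loss(z, z2, tau = 0.7)),
               ad_value(simclr_loss(z, z, tau = 0.7)), tolerance = 1e-12)
  expect_error(simclr_loss(list(v), list(v)), "at least 2")
})

test_that("contrastive loss matches the brute-force softmax oracle", {
  oracle <- function(z1, z2, tau) {
    n <- nrow(z1)
    cosv <- function(a, b) sum(a * b) / sqrt(sum(a^2) * sum(b^2))
    mean(vapply(seq_len(n), function(i) {
      pos <- exp(cosv(z1[i, ], z2[i, ]) / tau)
      den <- sum(vapply(setdiff(seq_len(n), i), function(j)
        exp(cosv(z1[i, ], z2[j, ]) / tau), numeric(1)))
      -log(pos / den)
    }, numeric(1)))
  }
  set.seed(2)
  for (rep in 1:20) {
    n <- sample(2:8, 1); d <- sample(2:5, 1); tau <- runif(1, 0.2, 1)
    z1 <- rmat(n, d); z2 <- rmat(n, d)
    expect_close(simclr_loss(z1, z2, tau), oracle(z1, z2, tau), 1e-6)
  }
})

test_that("auxiliary loss combines linearly with nonnegative weights", {
  expect_equal(ad_value(aux_loss(2, 3, 1, 0)), 2)
  expect_equal(ad_value(aux_loss(2, 3, 0, 0)), 0)
  expect_equal(ad_value(aux_loss(2, 3, 2, 1)), 2 * ad_value(aux_loss(2, 3, 1, 1)) - 3)
  expect_error(aux_loss(1, 1, -1, 0), "nonnegative")
})

test_that("momentum update interpolates parameter collections elementwise", {
  expect_equal(momentum_update(0, 2, m = 0.5), 1)
  th_m <- list(a = matrix(0, 2, 2), b = list(c = c(1, 1)))
  th <- list(a = matrix(2, 2, 2), b = list(c = c(3, 5)))
  expect_equal(momentum_update(th_m, th, m = 1), th_m)
  expect_equal(momentum_update(th_m, th, m = 0), th)
  half <- momentum_update(th_m, th, m = 0.5)
  expect_equal(half$a, matrix(1, 2, 2))
  expect_equal(half$b$c, c(2, 3))
  expect_error(momentum_update(list(a = 1:2), list(a = 1:3), 0.5), "shapes")
})

test_that("block masks are seeded, blockwise, and hit the target ratio", {
  m1 <- make_mask(c(16, 16, 16), 0.5, 4, seed = 9)
  m2 <- make_mask(c(16, 16, 16), 0.5, 4, seed = 9)
  expect_identical(m1, m2)
  frac <- sum(m1) / length(m1)
  expect_gte(frac, 0.5)
  expect_lte(frac, 0.5 + 4^3 / 16^3)
  # the ratio -> 0 limit is a single cube
  tiny <- make_mask(c(16, 16, 16), 1e-6, 4, seed = 2)
  expect_equal(sum(tiny), 4^3)
  expect_error(make_mask(c(8, 8, 8), 0.5, 9), "exceeds grid")
})

test_that("pretraining reduces the running auxiliary loss on phantoms", {
  co <- generate_cohort(fixture_config(n_samples = 24L, seed = 55L))
  wins <- 0L
  for (seed in c(1L, 2L, 3L)) {
    m <- fixture_model(seed = seed)
    cfg <- train_config(stage1_epochs = 3L, batch_size = 8L, seed = seed)
    m <- pretrain(m, co, cfg)
    aux <- vapply(m$history$stage1, `[[`, numeric(1), "aux")
    if (aux[3] < aux[1]) wins <- wins + 1L
  }
  expect_gte(wins, 2L)
})
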