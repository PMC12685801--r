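# Cross-view consistency, the view-aware contrastive loss, and the affine
# alignment module.

test_that("consistency loss is the mean squared pair distance", {
  z <- rmat(4, 3)
  expect_equal(ad_value(consistency_loss(z, z)), 0)
  expect_equal(ad_value(consistency_loss(rbind(c(1, 0)), rbind(c(0, 0)))), 1)
  zb <- rmat(4, 3)
  perm <- c(3, 1, 4, 2)
  expect_equal(ad_value(consistency_loss(z, zb)),
               ad_value(consistency_loss(z[perm, ], zb[perm, ])))
  expect_error(consistency_loss(z, zb[1:3, ]), "counts")
})

test_that("view contrastive loss shares the printed-denominator convention", {
  v <- rnorm(5)
  same <- lapply(1:3, function(i) v)
  expect_equal(ad_value(view_contrastive_loss(same, same, tau = 0.5)), log(2),
               tolerance = 1e-12)
  e <- diag(3)
  z <- lapply(1:3, function(i) e[i, ])
  expect_equal(ad_value(view_contrastive_loss(z, z, tau = 0.5)), -2 + log(2),
               tolerance = 1e-12)
  set.seed(6)
  z1 <- rmat(5, 4); z2 <- rmat(5, 4)
  expect_close(view_contrastive_loss(z1, z2, 0.6), simclr_loss(z1, z2, 0.6), 1e-12)
})

test_that("aligned consistency with identity aligner reduces to plain consistency", {
  co <- generate_cohort(fixture_config(n_samples = 3L, seed = 77L))
  m <- fixture_model()
  xa <- lapply(co, `[[`, "volume")
  xb <- lapply(co, `[[`, "view_pair")
  phi <- function(v) ad_value(lobenet:::t_gap(encode_region(v, m$params$enc, m$cfg$enc)))
  plain <- ad_value(consistency_loss(lapply(xa, phi), lapply(xb, phi)))
  al <- ad_value(aligned_consistency_loss(xa, xb, m$params$enc, m$cfg$enc,
                                          aligner = NULL))
  expect_equal(al, plain, tolerance = 1e-10)
  # x_a == x_b with identity alignment gives exactly zero
  expect_equal(ad_value(aligned_consistency_loss(xa, xa, m$params$enc, m$cfg$enc)), 0)
})

test_that("the affine module starts at identity and can be trained to undo jitter", {
  # fixture pairs with a known constant one-voxel shift
  co <- generate_cohort(fixture_config(n_samples = 6L, seed = 99L,
                                       noise_sd = 0.02, make_views = FALSE))
  xa <- lapply(co, `[[`, "volume")
  xb <- lapply(xa, shift_volume, dx = 1L)
  m <- fixture_model()
  al <- init_aligner_params()
  theta0 <- predict_affine(xa[[1]], xb[[1]], al)
  expect_equal(theta0, numeric(12)) # zero offsets = identity transform
  base <- ad_value(aligned_consistency_loss(xa, xb, m$params$enc, m$cfg$enc, NULL))
  wins <- 0L
  for (seed in 1:3) {
    alp <- init_aligner_params()
    opt <- NULL
    set.seed(seed)
    for (step in 1:30) {
      wrapped <- list(W = ad_param(alp$W), b = ad_param(alp$b))
      loss <- aligned_consistency_loss(xa, xb, m$params$enc, m$cfg$enc, wrapped)
      ad_backward(loss)
      g <- list(W = wrapped$W$grad, b = wrapped$b$grad)
      if (is.null(opt)) opt <- lobenet:::adam_init(alp)
      upd <- lobenet:::adam_step(alp, g, opt, lr = 0.02)
      alp <- upd$params; opt <- upd$state
    }
    final <- ad_value(aligned_consistency_loss(xa, xb, m$params$enc, m$cfg$enc, alp))
    if (final < base) wins <- wins + 1L
  }
  expect_gte(wins, 3L)
})

test_that("stage-2 consistency training shrinks held-out pair distances", {
  co <- generate_cohort(fixture_config(n_samples = 40L, seed = 13L))
  pc <- fixture_config(n_samples = 40L, seed = 13L)
  pair_dist <- function(res, studies) {
    m <- res$model
    mean(vapply(studies, function(st) {
      za <- ad_value(lobenet:::t_gap(encode_region(st$volume, m$params$enc, m$cfg$enc)))
      zb <- ad_value(lobenet:::t_gap(encode_region(st$view_pair, m$params$enc, m$cfg$enc)))
      sum((za - zb)^2)
    }, numeric(1)))
  }
  lam_off <- list(cons = 0, center = 0, mmd = 0, mask_tv = 0, patho = 0, ent = 0,
                  graph = 0, mono = 0, sym = 0, cooc = 0, zone = 0,
                  consist = 0, view_contr = 0)
  lam_on <- modifyList(lam_off, list(consist = 1, view_contr = 0.1))
  d_on <- c(); d_off <- c()
  for (seed in c(21L, 22L, 23L)) {
    mk <- function() build_model(pc, channels = 4L, blocks = 1L, d1 = 4L, d2 = 4L,
                                 seed = substream_seed(seed, "model"))
    cfg_on <- train_config(stage1_epochs = 0L, stage2_epochs = 4L, seed = seed,
                           lambdas = lam_on, use_momentum_targets = FALSE)
    cfg_off <- train_config(stage1_epochs = 0L, stage2_epochs = 4L, seed = seed,
                            lambdas = lam_off, use_momentum_targets = FALSE)
    r_on <- run_curriculum(co, pc, cfg_on, model = mk(), skip_stage1 = TRUE)
    r_off <- run_curriculum(co, pc, cfg_off, model = mk(), skip_stage1 = TRUE)
    held <- co[r_on$splits$test]
    d_on <- c(d_on, pair_dist(r_on, held))
    d_off <- c(d_off, pair_dist(r_off, held))
  }
  expect_lt(mean(d_on), mean(d_off))
})
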