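# Objective composition, metrics, the plateau scheduler, stratified
# splits, and curriculum plumbing.

test_that("compose_objective is the weighted dot product with NaN guards", {
  terms <- list(task = 2, cons = 3, center = 0.5)
  lam <- c(task = 1, cons = 0, center = 2)
  b <- compose_objective(terms, lam)
  expect_s3_class(b, "loss_bundle")
  expect_equal(ad_value(b$total), 2 + 2 * 0.5)
  expect_equal(unname(b$terms["cons"]), 0) # skipped but reported as 0
  # doubling every weight doubles the total at fixed terms
  b2 <- compose_objective(terms, lam * 2)
  expect_equal(ad_value(b2$total), 2 * ad_value(b$total))
  # random dot-product oracle
  set.seed(2)
  for (i in 1:20) {
    tm <- as.list(stats::setNames(rnorm(4), c("a", "b", "c", "d")))
    lm <- stats::setNames(runif(4), c("a", "b", "c", "d"))
    expect_close(ad_value(compose_objective(tm, lm)$total),
                 sum(unlist(tm) * lm), 1e-12)
  }
  expect_error(compose_objective(list(task = NaN), c(task = 1)), "task")
  expect_error(compose_objective(list(), c(task = 1)), "not computed")
})

test_that("classification metrics match hand-computed confusion tables", {
  # perfect predictions
  m <- compute_metrics(c(0.9, 0.8, 0.1, 0.2), c(1, 1, 0, 0))
  expect_equal(unlist(m), c(accuracy = 1, recall = 1, f1 = 1, auc = 1))
  # AUC by the rank statistic: scores (.9,.8,.3,.1), labels (1,0,1,0) -> 0.75
  expect_equal(compute_metrics(c(0.9, 0.8, 0.3, 0.1), c(1, 0, 1, 0))$auc, 0.75)
  # all-positive predictions on balanced labels
  m2 <- compute_metrics(c(0.9, 0.8, 0.7, 0.6), c(1, 0, 1, 0))
  expect_equal(m2$recall, 1)
  expect_equal(m2$accuracy, 0.5)
  expect_warning(m3 <- compute_metrics(c(0.2, 0.9), c(1, 1)), "single-class")
  expect_true(is.na(m3$auc))
  # brute-force AUC oracle over positive-negative pairs, with ties
  set.seed(3)
  for (i in 1:25) {
    s <- round(runif(20), 1)
    y <- rbinom(20, 1, 0.5)
    if (length(unique(y)) < 2) next
    pairs <- expand.grid(p = which(y == 1), n = which(y == 0))
    oracle <- mean(ifelse(s[pairs$p] > s[pairs$n], 1,
                          ifelse(s[pairs$p] == s[pairs$n], 0.5, 0)))
    expect_equal(compute_metrics(s, y)$auc, oracle, tolerance = 1e-12)
  }
})

test_that("rank-statistic AUC agrees with an established implementation", {
  skip_if_not_installed("pROC")
  set.seed(4)
  s <- rnorm(40); y <- rbinom(40, 1, 0.4)
  ours <- compute_metrics(s, y)$auc
  ref <- as.numeric(pROC::auc(pROC::roc(y, s, quiet = TRUE)))
  expect_equal(ours, ref, tolerance = 1e-12)
})

test_that("macro multiclass metrics average one-vs-rest statistics", {
  scores <- rbind(c(0.8, 0.1, 0.1),
                  c(0.2, 0.7, 0.1),
                  c(0.1, 0.2, 0.7),
                  c(0.5, 0.4, 0.1))
  labels <- c(0, 1, 2, 1)
  m <- compute_metrics(scores, labels)
  expect_equal(m$accuracy, 0.75)
  expect_equal(m$recall, mean(c(1, 0.5, 1))) # per-class recalls
})

test_that("the plateau scheduler decays after the configured patience", {
  st <- NULL
  vals <- c(0.5, 0.6, 0.6, 0.6, 0.6) # improvement then a 4-epoch plateau
  for (v in vals) st <- plateau_step(st, v, lr0 = 1e-3, patience = 3, factor = 0.1)
  expect_equal(st$lr, 1e-4) # decayed once after 3 stale epochs
  st <- plateau_step(st, 0.7, 1e-3, 3, 0.1) # improvement resets the counter
  expect_equal(st$wait, 0L)
  expect_equal(st$lr, 1e-4) # decay is not undone
})

test_that("stratified splits preserve class balance and are seeded", {
  labs <- rep(0:4, each = 20)
  s1 <- stratified_split(labs, c(0.8, 0.1, 0.1), seed = 3)
  s2 <- stratified_split(labs, c(0.8, 0.1, 0.1), seed = 3)
  expect_identical(s1, s2)
  expect_length(intersect(s1$train, s1$test), 0L)
  expect_length(intersect(s1$train, s1$val), 0L)
  expect_equal(sort(c(s1$train, s1$val, s1$test)), seq_along(labs))
  for (cl in 0:4) expect_equal(sum(labs[s1$train] == cl), 16)
})

test_that("k-fold splits partition the cohort with per-class balance", {
  labs <- rep(0:4, each = 20)
  folds <- kfold_splits(labs, k = 5, seed = 2)
  expect_identical(folds, kfold_splits(labs, k = 5, seed = 2))
  expect_equal(sort(unlist(folds)), seq_along(labs))
  for (f in folds) for (cl in 0:4) expect_equal(sum(labs[f] == cl), 4)
})

test_that("flatten/unflatten round-trips the trainable parameters", {
  m <- fixture_model()
  flat <- flatten_params(m$params)
  expect_gt(length(flat), 100)
  back <- unflatten_params(m$params, flat)
  expect_equal(back, m$params)
  flat2 <- flat + 1
  b2 <- unflatten_params(m$params, flat2)
  expect_equal(flatten_params(b2), flat + 1, ignore_attr = TRUE)
})

test_that("curriculum runs end to end and writes the metrics artifacts", {
  co <- generate_cohort(fixture_config(n_samples = 20L, seed = 17L))
  pc <- fixture_config(n_samples = 20L, seed = 17L)
  out <- withr::local_tempdir()
  cfg <- train_config(stage1_epochs = 1L, stage2_epochs = 2L, seed = 5L,
                      lambdas = list(mask_tv = 0, align = 0))
  m <- build_model(pc, channels = 4L, blocks = 1L, d1 = 4L, d2 = 4L,
                   seed = substream_seed(5L, "model"))
  res <- run_curriculum(co, pc, cfg, out_dir = out, model = m)
  expect_true(file.exists(file.path(out, "metrics.json")))
  expect_true(file.exists(file.path(out, "checkpoint.rds")))
  expect_true(file.exists(file.path(out, "zscore_clinical.json")))
  js <- jsonlite::read_json(file.path(out, "metrics.json"))
  expect_length(js$history$stage2, 2L)
  expect_true(is.finite(res$evaluation$metrics$accuracy))
  # stage 2 from random init also completes (smoke)
  res2 <- run_curriculum(co, pc, cfg, skip_stage1 = TRUE)
  expect_true(is.finite(res2$evaluation$metrics$accuracy))
})
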