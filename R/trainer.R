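# Two-stage curriculum trainer: stage 1 optimizes the auxiliary
# self-supervised objective (masked reconstruction + contrastive, with
# momentum-encoder targets); stage 2 attaches the task heads and optimizes
# the composite objective with the structural and knowledge-guided
# constraint terms. All randomness flows from the config seed through
# named substreams, so metric trajectories are bitwise reproducible.

#' Training configuration
#'
#' @param stage1_epochs,stage2_epochs epochs per stage.
#' @param batch_size minibatch size.
#' @param lr Adam learning rate.
#' @param weight_decay L2 weight decay added to gradients.
#' @param patience plateau patience (epochs without validation improvement).
#' @param lr_factor multiplicative learning-rate reduction on plateau.
#' @param lambdas named loss weights; any term not listed defaults to
#'   `reg_scale` (the task term defaults to 1).
#' @param reg_scale global scale of every regularizer's default weight, so
#'   the task loss dominates.
#' @param tau contrastive temperature.
#' @param momentum_m momentum-encoder EMA coefficient.
#' @param mask_ratio,mask_block occlusion mask parameters for stage 1.
#' @param delta ordinal margin for the monotonicity loss.
#' @param split train/validation/test fractions.
#' @param use_momentum_targets use momentum-encoder embeddings as
#'   contrastive and cross-view targets (online-only when FALSE).
#' @param seed integer root seed.
#' @return A `train_config` list.
#' @export
train_config <- function(stage1_epochs = 2L, stage2_epochs = 8L,
                         batch_size = 8L, lr = 1e-3, weight_decay = 1e-5,
                         patience = 5L, lr_factor = 0.1,
                         lambdas = list(), reg_scale = 0.1,
                         tau = 0.5, momentum_m = 0.99,
                         mask_ratio = 0.5, mask_block = 4L, delta = 0.1,
                         split = c(0.8, 0.1, 0.1),
                         use_momentum_targets = TRUE, seed = 1L) {
  stopifnot(lr > 0, abs(sum(split) - 1) < 1e-8)
  structure(list(stage1_epochs = as.integer(stage1_epochs),
                 stage2_epochs = as.integer(stage2_epochs),
                 batch_size = as.integer(batch_size), lr = lr,
                 weight_decay = weight_decay, patience = as.integer(patience),
                 lr_factor = lr_factor, lambdas = lambdas,
                 reg_scale = reg_scale, tau = tau, momentum_m = momentum_m,
                 mask_ratio = mask_ratio, mask_block = as.integer(mask_block),
                 delta = delta, split = split,
                 use_momentum_targets = isTRUE(use_momentum_targets),
                 seed = as.integer(seed)),
            class = "train_config")
}

# Default stage-2 lambda map. Every regularizer defaults to reg_scale
# times a per-term normalizer chosen so its typical contribution sits one
# order of magnitude below the task loss: the raw terms live on wildly
# different scales (the mask-TV term sums |differences| over ~1e4 voxel
# pairs, the zone term sums squared heatmap mass over the grid, while the
# hinge and centre terms are O(1)). The aligner weight defaults to 0; Eq-38
# style alignment replaces the plain consistency term only when enabled.
default_lambdas <- function(config) {
  rel <- c(task = NA, cons = 1, center = 1, mmd = 0.1, mask_tv = 1e-4,
           patho = 1, ent = 0.2, graph = 0.1, mono = 1, sym = 0.1,
           cooc = 1, zone = 0.01, consist = 0.5, view_contr = 0.2, align = 0)
  lam <- config$reg_scale * rel
  lam["task"] <- 1
  for (nm in names(config$lambdas)) lam[nm] <- config$lambdas[[nm]]
  lam
}

#' Compose the weighted training objective
#'
#' `total = sum_t lambda_t * term_t`. Terms whose weight is zero are
#' reported as 0 and excluded from the sum (callers may skip computing
#' them). Any non-finite active term aborts with the term's name.
#'
#' @param terms named list of scalar loss terms (numeric or adnodes);
#'   entries may be NULL when their weight is zero.
#' @param lambdas named numeric weights.
#' @return A `loss_bundle`: list with numeric `terms`, `lambdas`, and
#'   `total` (adnode during training).
#' @export
compose_objective <- function(terms, lambdas) {
  active <- names(lambdas)[lambdas != 0]
  missing <- setdiff(active, names(terms)[!vapply(terms, is.null, logical(1))])
  if (length(missing))
    stop(sprintf("compose_objective: active term(s) not computed: %s",
                 paste(missing, collapse = ", ")))
  total <- NULL
  vals <- stats::setNames(numeric(length(lambdas)), names(lambdas))
  for (nm in names(lambdas)) {
    if (lambdas[[nm]] == 0) next
    v <- ad_value(terms[[nm]])
    if (!is.finite(v))
      stop(sprintf("compose_objective: loss term '%s' is not finite (%g)", nm, v))
    vals[nm] <- v
    wterm <- t_mul(lambdas[[nm]], terms[[nm]])
    total <- if (is.null(total)) wterm else t_add(total, wterm)
  }
  structure(list(terms = vals, lambdas = lambdas, total = total),
            class = "loss_bundle")
}

# ---- optimizer -------------------------------------------------------------

adam_init <- function(params) {
  list(m = params_map(params, function(x, nm) zeros_like(x)),
       v = params_map(params, function(x, nm) zeros_like(x)),
       t = 0L)
}

adam_step <- function(params, grads, state, lr, weight_decay = 0,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  t <- state$t
  step_leaf <- function(p, g, m, v) {
    g <- g + weight_decay * p
    m <- beta1 * m + (1 - beta1) * g
    v <- beta2 * v + (1 - beta2) * g * g
    mh <- m / (1 - beta1^t)
    vh <- v / (1 - beta2^t)
    list(p = p - lr * mh / (sqrt(vh) + eps), m = m, v = v)
  }
  walk <- function(p, g, m, v) {
    for (nm in names(p)) {
      x <- p[[nm]]
      if (nm %in% PARAM_SKIP || is.character(x)) next
      if (is.list(x)) {
        res <- walk(x, g[[nm]], m[[nm]], v[[nm]])
        p[[nm]] <- res$p; m[[nm]] <- res$m; v[[nm]] <- res$v
        g[[nm]] <- res$g
      } else {
        res <- step_leaf(x, g[[nm]], m[[nm]], v[[nm]])
        p[[nm]] <- res$p; m[[nm]] <- res$m; v[[nm]] <- res$v
      }
    }
    list(p = p, g = g, m = m, v = v)
  }
  res <- walk(params, grads, state$m, state$v)
  list(params = res$p, state = list(m = res$m, v = res$v, t = t))
}

#' Plateau learning-rate scheduler step
#'
#' Reduces the learning rate by `factor` after `patience` epochs without
#' improvement of the monitored value (higher is better).
#'
#' @param state NULL to initialize, else the state returned previously.
#' @param value monitored validation value for this epoch.
#' @param lr0 initial learning rate.
#' @param patience epochs to wait.
#' @param factor multiplicative reduction.
#' @return State list with current `lr`, `best`, `wait`.
#' @export
plateau_step <- function(state, value, lr0, patience = 5L, factor = 0.1) {
  if (is.null(state)) state <- list(lr = lr0, best = -Inf, wait = 0L)
  if (value > state$best + 1e-12) {
    state$best <- value
    state$wait <- 0L
  } else {
    state$wait <- state$wait + 1L
    if (state$wait >= patience) {
      state$lr <- state$lr * factor
      state$wait <- 0L
    }
  }
  state
}

#' Stratified train/validation/test split
#'
#' @param labels class labels.
#' @param split fractions summing to 1.
#' @param seed integer seed.
#' @return List of integer index vectors `train`, `val`, `test`.
#' @export
stratified_split <- function(labels, split = c(0.8, 0.1, 0.1), seed = 1L) {
  with_seed(seed, {
    idx <- list(train = integer(0), val = integer(0), test = integer(0))
    for (cl in unique(labels)) {
      ids <- sample(which(labels == cl))
      n <- length(ids)
      n_tr <- round(split[1] * n)
      n_va <- max(1L, round(split[2] * n))
      if (n_tr + n_va >= n) n_tr <- max(1L, n - n_va - 1L)
      idx$train <- c(idx$train, ids[seq_len(n_tr)])
      idx$val <- c(idx$val, ids[n_tr + seq_len(n_va)])
      idx$test <- c(idx$test, ids[(n_tr + n_va + 1L):n])
    }
    lapply(idx, sort)
  })
}

#' Stratified k-fold split
#'
#' Offered alongside the default train/validation/test split for
#' cross-validated runs; fold assignment is stratified by class and
#' seeded.
#'
#' @param labels class labels.
#' @param k number of folds (default 5).
#' @param seed integer seed.
#' @return List of k integer index vectors (the held-out fold per split).
#' @export
kfold_splits <- function(labels, k = 5L, seed = 1L) {
  with_seed(seed, {
    fold <- integer(length(labels))
    for (cl in unique(labels)) {
      ids <- sample(which(labels == cl))
      fold[ids] <- rep_len(seq_len(k), length(ids))
    }
    lapply(seq_len(k), function(f) sort(which(fold == f)))
  })
}

# ---- stage 1 ---------------------------------------------------------------

stage1_batch_loss <- function(model, batch, wrapped, config, step_seed) {
  grid <- dim(batch[[1]]$volume)
  recon_terms <- list()
  z1 <- list(); z2 <- list()
  for (i in seq_along(batch)) {
    st <- batch[[i]]
    mask <- make_mask(grid, config$mask_ratio, config$mask_block,
                      seed = step_seed + i)
    occluded <- st$volume * (1 - mask)
    feat <- encode_region(occluded, wrapped$enc, model$cfg$enc)
    recon <- decode_volume(feat, wrapped$dec)
    recon_terms <- c(recon_terms,
                     list(masked_recon_loss(st$volume, recon, mask)))
    z1[[i]] <- t_gap(feat)
    other <- st$view_pair %||% st$volume
    z2[[i]] <- if (config$use_momentum_targets) momentum_embed(model, other)
    else t_gap(encode_region(other, wrapped$enc, model$cfg$enc))
  }
  recon <- t_div(Reduce(t_add, recon_terms), length(recon_terms))
  contrast <- if (length(batch) >= 2) simclr_loss(z1, z2, tau = config$tau) else 0
  list(loss = aux_loss(recon, contrast), recon = ad_value(recon),
       simclr = ad_value(contrast))
}

#' Stage-1 self-supervised pretraining
#'
#' Optimizes the weighted masked-reconstruction + contrastive objective on
#' the training studies; the momentum encoder is EMA-updated every step and
#' provides the contrastive targets.
#'
#' @param model a [build_model()] object.
#' @param studies training studies.
#' @param config a [train_config()].
#' @return The model with pretrained encoder/decoder and a `stage1`
#'   history (mean epoch losses) in `model$history`.
#' @export
pretrain <- function(model, studies, config) {
  opt <- adam_init(model$params)
  history <- list()
  seed0 <- substream_seed(config$seed, "stage1")
  with_seed(seed0, {
    for (epoch in seq_len(config$stage1_epochs)) {
      ord <- sample(length(studies))
      ep_loss <- c()
      for (b0 in seq(1, length(ord), by = config$batch_size)) {
        batch <- studies[ord[b0:min(b0 + config$batch_size - 1L, length(ord))]]
        wrapped <- wrap_params(model$params)
        res <- stage1_batch_loss(model, batch, wrapped, config,
                                 step_seed = seed0 + epoch * 10000L + b0)
        if (is_adnode(res$loss)) {
          ad_backward(res$loss)
          upd <- adam_step(model$params, collect_grads(wrapped), opt,
                           lr = config$lr, weight_decay = config$weight_decay)
          model$params <- upd$params
          opt <- upd$state
          model$state$momentum_enc <- momentum_update(
            model$state$momentum_enc, model$params$enc, m = config$momentum_m)
        }
        ep_loss <- c(ep_loss, ad_value(res$loss))
      }
      history[[epoch]] <- list(epoch = epoch, aux = mean(ep_loss))
    }
  })
  model$history$stage1 <- history
  model
}

# ---- stage 2 ---------------------------------------------------------------

stage2_batch_loss <- function(model, batch, wrapped, config, lambdas) {
  cfg <- model$cfg
  outs <- lapply(batch, function(st) forward_study(model, st, wrapped, train = TRUE))
  n <- length(batch)
  terms <- list()
  lam_on <- function(nm) lambdas[[nm]] != 0
  if (lam_on("task"))
    terms$task <- t_div(Reduce(t_add, Map(function(o, st) ce_loss(o$logits, st$class_label),
                                          outs, batch)), n)
  if (lam_on("cons")) {
    alpha_s <- simplex_weights(wrapped$simplex_logits)
    terms$cons <- hierarchical_consistency(
      lapply(outs, `[[`, "v_glob"), lapply(outs, `[[`, "h"), alpha_s)
  }
  if (lam_on("center")) {
    labs <- vapply(batch, `[[`, numeric(1), "class_label")
    terms$center <- center_loss(lapply(outs, `[[`, "z"), labs, model$state$centroids)
  }
  if (lam_on("mmd")) {
    coh <- vapply(batch, `[[`, character(1), "cohort")
    za <- lapply(outs[coh == "A"], `[[`, "z")
    zb <- lapply(outs[coh == "B"], `[[`, "z")
    terms$mmd <- if (length(za) && length(zb)) mmd_linear(za, zb) else 0
  }
  if (lam_on("mask_tv"))
    terms$mask_tv <- t_div(Reduce(t_add, lapply(outs, function(o)
      mask_tv(o$fmaps, model$state$masks_ds))), n)
  if (lam_on("patho"))
    terms$patho <- patho_regression_loss(
      vapply(batch, `[[`, numeric(1), "severity"), lapply(outs, `[[`, "shat"))
  if (lam_on("ent"))
    terms$ent <- t_div(Reduce(t_add, lapply(outs, function(o)
      entropy_regularizer(o$alpha))), n)
  if (lam_on("graph"))
    terms$graph <- t_div(Reduce(t_add, lapply(outs, function(o)
      graph_smoothness(o$hp, cfg$adj))), n)
  if (lam_on("mono"))
    terms$mono <- monotonicity_loss(lapply(outs, `[[`, "shat"),
                                    vapply(batch, `[[`, numeric(1), "severity"),
                                    delta = config$delta)
  if (lam_on("sym")) {
    left <- which(cfg$side == "L"); right <- which(cfg$side == "R")
    terms$sym <- if (length(left) && length(right)) {
      fl <- lapply(outs, function(o)
        t_div(Reduce(t_add, o$h[left]), length(left)))
      fr <- lapply(outs, function(o)
        t_div(Reduce(t_add, o$h[right]), length(right)))
      symmetry_loss(fl, fr, Tmat = wrapped$sym_T)
    } else 0
  }
  if (lam_on("cooc"))
    terms$cooc <- cooccurrence_loss(lapply(outs, `[[`, "ml_pred"), model$state$cooc)
  if (lam_on("zone"))
    terms$zone <- zone_loss(lapply(outs, `[[`, "heatmap"), model$state$zone)
  has_views <- all(vapply(batch, function(st) !is.null(st$view_pair), logical(1)))
  if (lam_on("consist") || lam_on("view_contr")) {
    if (has_views) {
      za <- lapply(outs, `[[`, "v_glob")
      zb <- lapply(batch, function(st) {
        if (config$use_momentum_targets) momentum_embed(model, st$view_pair)
        else t_gap(encode_region(st$view_pair, wrapped$enc, cfg$enc))
      })
      if (lam_on("consist")) terms$consist <- consistency_loss(za, zb)
      if (lam_on("view_contr") && n >= 2)
        terms$view_contr <- view_contrastive_loss(za, zb, tau = config$tau)
      else if (lam_on("view_contr")) terms$view_contr <- 0
    } else {
      if (lam_on("consist")) terms$consist <- 0
      if (lam_on("view_contr")) terms$view_contr <- 0
    }
  }
  if (lam_on("align")) {
    terms$align <- if (has_views)
      aligned_consistency_loss(lapply(batch, `[[`, "volume"),
                               lapply(batch, `[[`, "view_pair"),
                               wrapped$enc, cfg$enc, aligner = wrapped$aligner)
    else 0
  }
  list(bundle = compose_objective(terms, lambdas), outs = outs)
}

# numeric embeddings/predictions for a set of studies (no gradients)
predict_studies <- function(model, studies) {
  lapply(studies, function(st) {
    o <- forward_study(model, st, params = NULL, train = FALSE)
    probs <- ad_value(t_softmax(o$logits))
    list(probs = probs, pred = which.max(probs) - 1L,
         alpha = vapply(o$alpha, ad_value, numeric(1)),
         z = ad_value(o$z), v_glob = ad_value(o$v_glob),
         shat = ad_value(o$shat))
  })
}

#' Fine-tune under the composite objective (stage 2)
#'
#' Attaches the task heads to the (optionally pretrained) encoder and
#' optimizes the weighted sum of the task loss and all active structural
#' and knowledge-guided terms. Class centroids are initialized from a
#' forward pass and EMA-updated per step; the co-occurrence matrix is
#' estimated from the training label table.
#'
#' @param model a [build_model()] object (typically after [pretrain()]).
#' @param studies training studies (tabular vectors standardized via
#'   `model$state$zscore`).
#' @param config a [train_config()].
#' @param val_studies held-out studies monitored by the plateau scheduler.
#' @return The model, with `model$history$stage2` holding per-epoch loss
#'   terms, validation accuracy, and the learning rate.
#' @export
finetune <- function(model, studies, config, val_studies = NULL) {
  lambdas <- default_lambdas(config)
  if (lambdas[["cooc"]] != 0) {
    ml <- t(vapply(studies, `[[`, numeric(model$cfg$phantom$n_labels), "multilabel"))
    model$state$cooc <- estimate_cooccurrence(ml)
  }
  # centroid warm start so every class has a centroid before the first step
  if (lambdas[["center"]] != 0) {
    preds <- predict_studies(model, studies)
    zmat <- do.call(rbind, lapply(preds, `[[`, "z"))
    labs <- vapply(studies, `[[`, numeric(1), "class_label")
    model$state$centroids <- update_centroids(list(), zmat, labs, rate = 1)
  }
  opt <- adam_init(model$params)
  sched <- NULL
  history <- list()
  seed0 <- substream_seed(config$seed, "stage2")
  with_seed(seed0, {
    lr <- config$lr
    for (epoch in seq_len(config$stage2_epochs)) {
      ord <- sample(length(studies))
      ep_terms <- NULL
      for (b0 in seq(1, length(ord), by = config$batch_size)) {
        batch <- studies[ord[b0:min(b0 + config$batch_size - 1L, length(ord))]]
        wrapped <- wrap_params(model$params)
        res <- stage2_batch_loss(model, batch, wrapped, config, lambdas)
        ad_backward(res$bundle$total)
        upd <- adam_step(model$params, collect_grads(wrapped), opt,
                         lr = lr, weight_decay = config$weight_decay)
        model$params <- upd$params
        opt <- upd$state
        model$state$momentum_enc <- momentum_update(
          model$state$momentum_enc, model$params$enc, m = config$momentum_m)
        if (lambdas[["center"]] != 0) {
          zmat <- do.call(rbind, lapply(res$outs, function(o) ad_value(o$z)))
          labs <- vapply(batch, `[[`, numeric(1), "class_label")
          model$state$centroids <- update_centroids(model$state$centroids,
                                                    zmat, labs, rate = 0.1)
        }
        # tabular normalization statistics follow the data seen this step
        for (wh in c("clinical", "metadata")) {
          xs <- do.call(rbind, lapply(batch, function(st)
            std_tabular(st, model$state)[[wh]]))
          bn <- update_bn_stats(model$params$tab[[wh]], xs)
          model$params$tab[[wh]]$run_mean <- bn$run_mean
          model$params$tab[[wh]]$run_var <- bn$run_var
        }
        ep_terms <- if (is.null(ep_terms)) res$bundle$terms
        else ep_terms + res$bundle$terms
      }
      n_batches <- ceiling(length(ord) / config$batch_size)
      entry <- list(epoch = epoch, lr = lr,
                    terms = as.list(ep_terms / n_batches))
      if (!is.null(val_studies)) {
        vp <- predict_studies(model, val_studies)
        acc <- mean(vapply(vp, `[[`, integer(1), "pred") ==
                      vapply(val_studies, `[[`, numeric(1), "class_label"))
        sched <- plateau_step(sched, acc, lr0 = config$lr,
                              patience = config$patience,
                              factor = config$lr_factor)
        lr <- sched$lr
        entry$val_accuracy <- acc
      }
      history[[epoch]] <- entry
    }
  })
  model$history$stage2 <- history
  model
}

#' Classification metrics
#'
#' Accuracy, recall, F1 and AUC. For binary labels, `scores` is a vector of
#' positive-class scores thresholded at 0.5; for multiclass, a matrix of
#' per-class scores (argmax prediction) with macro (one-vs-rest) averaging.
#' AUC uses the rank statistic over score-label pairs with ties averaged;
#' with a single observed class it is NA with a warning.
#'
#' @param scores numeric vector (binary) or n x C matrix (multiclass).
#' @param labels integer labels (0-based for multiclass, 0/1 for binary).
#' @return Named list `accuracy`, `recall`, `f1`, `auc`.
#' @export
compute_metrics <- function(scores, labels) {
  auc_rank <- function(s, y) {
    n1 <- sum(y == 1); n0 <- sum(y == 0)
    if (n1 == 0 || n0 == 0) {
      warning("compute_metrics: AUC undefined for single-class labels")
      return(NA_real_)
    }
    r <- rank(s, ties.method = "average")
    (sum(r[y == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
  }
  prf <- function(pred, y) { # one-vs-rest recall/F1 for a single class
    tp <- sum(pred == 1 & y == 1)
    fn <- sum(pred == 0 & y == 1)
    fp <- sum(pred == 1 & y == 0)
    rec <- if (tp + fn == 0) NA_real_ else tp / (tp + fn)
    prec <- if (tp + fp == 0) 0 else tp / (tp + fp)
    f1 <- if (is.na(rec) || prec + rec == 0) 0 else 2 * prec * rec / (prec + rec)
    c(rec = rec, f1 = f1)
  }
  if (is.matrix(scores)) {
    pred <- max.col(scores, ties.method = "first") - 1L
    classes <- sort(unique(labels))
    per <- vapply(classes, function(cl)
      prf(as.integer(pred == cl), as.integer(labels == cl)), numeric(2))
    aucs <- vapply(classes, function(cl)
      auc_rank(scores[, cl + 1L], as.integer(labels == cl)), numeric(1))
    list(accuracy = mean(pred == labels),
         recall = mean(per["rec", ], na.rm = TRUE),
         f1 = mean(per["f1", ]),
         auc = mean(aucs))
  } else {
    pred <- as.integer(scores >= 0.5)
    per <- prf(pred, labels)
    list(accuracy = mean(pred == labels),
         recall = unname(per["rec"]),
         f1 = unname(per["f1"]),
         auc = auc_rank(scores, labels))
  }
}

#' Evaluate a trained model on held-out studies
#'
#' @param model trained model.
#' @param studies held-out studies.
#' @return List with `metrics` (accuracy/recall/F1/AUC on the class task),
#'   `attention_localization` (fraction of studies whose lesioned lobe
#'   receives the maximal gated attention weight), `severity_mae`, and the
#'   per-study predictions.
#' @export
evaluate_model <- function(model, studies) {
  preds <- predict_studies(model, studies)
  labs <- vapply(studies, `[[`, numeric(1), "class_label")
  scores <- do.call(rbind, lapply(preds, `[[`, "probs"))
  loc <- mean(vapply(seq_along(studies), function(i)
    which.max(preds[[i]]$alpha) == studies[[i]]$region, logical(1)))
  sev <- vapply(studies, `[[`, numeric(1), "severity")
  shat <- vapply(preds, `[[`, numeric(1), "shat")
  list(metrics = compute_metrics(scores, labs),
       attention_localization = loc,
       severity_mae = mean(abs(shat - sev)),
       predictions = preds)
}

#' Run the full two-stage curriculum
#'
#' Splits the cohort (stratified by class), fits tabular z-score
#' standardization on the training split, pretrains (stage 1), fine-tunes
#' under the composite objective (stage 2), and evaluates on the test
#' split. With `out_dir`, writes per-epoch `metrics.json`, the parameter
#' checkpoint, and the standardization parameters.
#'
#' @param studies a phantom cohort (list of studies) or a cohort directory
#'   written by [write_cohort()].
#' @param phantom_cfg the generating [phantom_config()] (read from the
#'   manifest when `studies` is a directory).
#' @param config a [train_config()].
#' @param out_dir optional output directory.
#' @param model optional pre-built model (e.g. with custom architecture).
#' @param skip_stage1 start stage 2 from random initialization.
#' @return List with `model`, `evaluation` (test-split results), `splits`,
#'   and `history`.
#' @export
run_curriculum <- function(studies, phantom_cfg = NULL, config = train_config(),
                           out_dir = NULL, model = NULL, skip_stage1 = FALSE) {
  if (is.character(studies)) {
    dir <- studies
    manifest <- jsonlite::read_json(file.path(dir, "manifest.json"),
                                    simplifyVector = TRUE)
    phantom_cfg <- do.call(phantom_config, manifest$config[
      setdiff(names(manifest$config), character(0))])
    studies <- read_cohort(dir)
  }
  stopifnot(!is.null(phantom_cfg))
  if (is.null(model))
    model <- build_model(phantom_cfg, seed = substream_seed(config$seed, "model"))
  labs <- vapply(studies, `[[`, numeric(1), "class_label")
  splits <- stratified_split(labs, config$split,
                             seed = substream_seed(config$seed, "split"))
  tr <- studies[splits$train]
  model$state$zscore <- list(
    clinical = zscore_fit(do.call(rbind, lapply(tr, `[[`, "clinical"))),
    metadata = zscore_fit(do.call(rbind, lapply(tr, `[[`, "metadata"))))
  if (!skip_stage1 && config$stage1_epochs > 0)
    model <- pretrain(model, tr, config)
  model <- finetune(model, tr, config, val_studies = studies[splits$val])
  evaluation <- evaluate_model(model, studies[splits$test])
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    saveRDS(model$params, file.path(out_dir, "checkpoint.rds"))
    zscore_write(model$state$zscore$clinical, file.path(out_dir, "zscore_clinical.json"))
    zscore_write(model$state$zscore$metadata, file.path(out_dir, "zscore_metadata.json"))
    jsonlite::write_json(
      list(config = unclass(config), seed = config$seed,
           history = model$history,
           test_metrics = evaluation$metrics,
           attention_localization = evaluation$attention_localization),
      file.path(out_dir, "metrics.json"), auto_unbox = TRUE, digits = NA,
      pretty = TRUE, force = TRUE)
  }
  list(model = model, evaluation = evaluation, splits = splits,
       history = model$history)
}
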