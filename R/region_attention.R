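# Region decomposition, the shared volumetric encoder, and gated region
# attention. All forward functions accept plain arrays (inference) or
# adnodes (training); encoder weights are shared across regions by
# construction, since the same parameter objects are applied to every one.

#' Configuration of the shared 3D convolutional encoder
#'
#' A stride-2 stem convolution followed by `blocks` residual blocks
#' (x + conv(GELU(conv(x)))), all with isotropic odd kernels. Pooled
#' spatial dims are `grid/2` per axis.
#'
#' @param channels number of feature channels C.
#' @param blocks number of residual blocks.
#' @param kernel odd kernel edge length.
#' @param bias include bias terms (a bias-free encoder maps zero volumes to
#'   zero features exactly).
#' @return An `encoder_config` list.
#' @export
encoder_config <- function(channels = 16L, blocks = 2L, kernel = 3L, bias = TRUE) {
  stopifnot(channels >= 1, blocks >= 1, kernel %% 2 == 1)
  structure(list(channels = as.integer(channels), blocks = as.integer(blocks),
                 kernel = as.integer(kernel), bias = isTRUE(bias)),
            class = "encoder_config")
}

#' Initialize encoder parameters
#' @param config an [encoder_config()].
#' @param seed integer seed for the weight draw.
#' @return Named list of numeric arrays (stem + per-block conv weights).
#' @export
init_encoder_params <- function(config, seed = 1L) {
  k <- config$kernel; C <- config$channels
  with_seed(seed, {
    p <- list()
    he <- function(fan_in, dims) array(rnorm(prod(dims), sd = sqrt(2 / fan_in)), dim = dims)
    p$stem_w <- he(k^3, c(k, k, k, 1L, C))
    if (config$bias) p$stem_b <- numeric(C)
    for (b in seq_len(config$blocks)) {
      p[[sprintf("blk%d_w1", b)]] <- he(k^3 * C, c(k, k, k, C, C))
      p[[sprintf("blk%d_w2", b)]] <- he(k^3 * C, c(k, k, k, C, C))
      if (config$bias) {
        p[[sprintf("blk%d_b1", b)]] <- numeric(C)
        p[[sprintf("blk%d_b2", b)]] <- numeric(C)
      }
    }
    p
  })
}

#' Decompose a volume into masked region subvolumes
#'
#' Subvolume k is the elementwise product of the volume with binary mask k;
#' voxels outside the mask are exactly zero.
#'
#' @param volume 3D array (or adnode).
#' @param masks list of K binary arrays with the volume's dimensions.
#' @return List of K region subvolumes.
#' @export
decompose_regions <- function(volume, masks) {
  vd <- dim(ad_value(volume))
  lapply(seq_along(masks), function(k) {
    m <- masks[[k]]
    if (!identical(dim(m), vd))
      stop(sprintf("decompose_regions: mask %d has dims (%s) but volume has (%s)",
                   k, paste(dim(m), collapse = "x"), paste(vd, collapse = "x")))
    t_mul(volume, m)
  })
}

#' Encode a (sub)volume with the shared 3D convolutional encoder
#'
#' @param subvolume 3D array (or adnode) on the configured grid.
#' @param params encoder parameters from [init_encoder_params()] (numeric
#'   arrays or adnodes; the same objects must be passed for every region to
#'   honour the weight-sharing contract).
#' @param config the [encoder_config()].
#' @return Feature tensor of dim `(H', W', D', C)` with `H' = H/2`.
#' @export
encode_region <- function(subvolume, params, config) {
  v <- subvolume
  d <- dim(ad_value(v))
  if (length(d) == 3L) {
    if (is_adnode(v)) {
      dv <- ad_value(v); dim(dv) <- c(d, 1L)
      v <- ad_make(dv, list(subvolume), function(g) {
        if (!is.null(dim(g))) dim(g) <- d
        list(g)
      })
    } else dim(v) <- c(d, 1L)
    d <- c(d, 1L)
  }
  if (any(d[1:3] < config$kernel))
    stop(sprintf("encode_region: grid (%s) is smaller than the receptive-field minimum (kernel %d)",
                 paste(d[1:3], collapse = "x"), config$kernel))
  pad <- (config$kernel - 1L) %/% 2L
  x <- t_conv3d(v, params$stem_w, stride = 2L, pad = pad)
  if (config$bias) x <- t_bias4(x, params$stem_b)
  x <- t_gelu(x)
  for (b in seq_len(config$blocks)) {
    y <- t_conv3d(x, params[[sprintf("blk%d_w1", b)]], stride = 1L, pad = pad)
    if (config$bias) y <- t_bias4(y, params[[sprintf("blk%d_b1", b)]])
    y <- t_gelu(y)
    y <- t_conv3d(y, params[[sprintf("blk%d_w2", b)]], stride = 1L, pad = pad)
    if (config$bias) y <- t_bias4(y, params[[sprintf("blk%d_b2", b)]])
    x <- t_add(x, y)
  }
  x
}

#' Initialize gated-attention parameters
#' @param channels descriptor length C.
#' @param gate_dim hidden width of the gate (default C).
#' @param scale multiplier on the default weight scale; pooled descriptors
#'   are small in magnitude after global pooling, so a steeper gate at
#'   initialization gives the regions distinguishable weights from the
#'   first step.
#' @param seed integer seed.
#' @return List with projection `Wg` (gate_dim x C) and gate vector `w`.
#' @export
init_attention_params <- function(channels, gate_dim = channels, scale = 1,
                                  seed = 1L) {
  with_seed(seed, list(
    Wg = matrix(rnorm(gate_dim * channels, sd = scale * sqrt(1 / channels)),
                gate_dim, channels),
    w = rnorm(gate_dim, sd = scale * sqrt(1 / gate_dim))))
}

#' Gated attention weight for each region
#'
#' `alpha_k = sigmoid(w' tanh(Wg h_k))`: each weight depends only on its own
#' region's pooled descriptor (spatial disentanglement), so the weights are
#' independent sigmoid gates in \[0, 1\] and do not sum to one.
#'
#' @param pooled list of K pooled descriptors (length-C vectors or adnodes).
#' @param params list with `Wg` and `w` (see [init_attention_params()]).
#' @return List of K scalar weights (numeric or adnodes, matching inputs).
#' @export
gated_attention <- function(pooled, params) {
  if (is.matrix(pooled)) pooled <- lapply(seq_len(nrow(pooled)), function(i) pooled[i, ])
  lapply(pooled, function(h) {
    stopifnot(all(is.finite(ad_value(h))))
    t_sigmoid(t_dot(params$w, t_tanh(t_matvec(params$Wg, h))))
  })
}

#' Attention-weighted regional summary
#'
#' The summary is `sum_k alpha_k h_k`. With `normalize = TRUE` the weights are first
#' divided by their sum, turning the gated sum into a true convex
#' combination.
#'
#' @param pooled list of K length-C descriptors.
#' @param weights list (or numeric vector) of K weights in \[0, 1\].
#' @param normalize divide weights by their sum first.
#' @return Length-C summary vector.
#' @export
attended_summary <- function(pooled, weights, normalize = FALSE) {
  if (is.matrix(pooled)) pooled <- lapply(seq_len(nrow(pooled)), function(i) pooled[i, ])
  if (is.numeric(weights) && length(weights) == length(pooled) && !is_adnode(weights))
    weights <- as.list(weights)
  stopifnot(length(weights) == length(pooled))
  if (normalize) {
    tot <- Reduce(t_add, weights)
    if (ad_value(tot) == 0)
      stop("attended_summary: all-zero weights; the normalized convex combination is undefined")
    weights <- lapply(weights, function(a) t_div(a, tot))
  }
  Reduce(t_add, Map(function(a, h) t_mul(a, h), weights, pooled))
}

#' Entropy sparsity regularizer over attention weights
#'
#' Weights are normalized to a distribution p internally. The default
#' convention returns the Shannon entropy `H(p) = -sum p log p`, so that
#' minimizing the regularizer sharpens the attention distribution;
#' `as_printed = TRUE` returns `sum p log p` (its negation). `0 log 0` is
#' treated as 0.
#'
#' @param weights nonnegative weights, not all zero (numeric vector, list,
#'   or adnodes).
#' @param as_printed return `sum p log p` instead of `H(p)`.
#' @return Scalar regularizer value.
#' @export
entropy_regularizer <- function(weights, as_printed = FALSE) {
  if (is.list(weights)) {
    tracked <- any(vapply(weights, is_adnode, logical(1)))
    weights <- if (tracked) t_concat(weights) else unlist(lapply(weights, ad_value))
  }
  wv <- ad_value(weights)
  if (any(wv < 0)) stop("entropy_regularizer: weights must be nonnegative")
  if (sum(wv) == 0) stop("entropy_regularizer: weights must not all be zero")
  if (is_adnode(weights)) {
    p <- t_div(weights, t_sum(weights))
    plogp <- t_sum(t_mul(p, t_log(p))) # gates are strictly positive in training
  } else {
    p <- wv / sum(wv)
    plogp <- sum(ifelse(p > 0, p * log(p), 0))
  }
  if (as_printed) plogp else t_neg(plogp)
}

#' Dropout over attention weights
#'
#' Active only in training mode: zeroes each weight independently with the
#' given rate and rescales survivors by `1/(1 - rate)` (inverted dropout).
#' Draws from the current RNG stream, so seeding is the trainer's job.
#'
#' @param weights list of K scalar weights.
#' @param rate dropout rate in \[0, 1).
#' @param train logical; identity when FALSE.
#' @return List of K weights.
#' @export
attention_dropout <- function(weights, rate = 0.1, train = FALSE) {
  if (!train || rate <= 0) return(weights)
  keep <- (runif(length(weights)) >= rate) / (1 - rate)
  Map(function(a, k) t_mul(a, k), weights, as.list(keep))
}
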