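# Multi-modal fusion: volumetric descriptor + projected clinical and
# metadata vectors, concatenated in fixed order. Robust to missing
# modalities by zero-filling flagged blocks.

#' Global average pooling of a feature tensor
#'
#' Channelwise mean over all spatial positions of a `(H', W', D', C)`
#' tensor.
#'
#' @param x 4D feature tensor (or adnode).
#' @return Length-C descriptor.
#' @export
global_average_pool <- function(x) {
  stopifnot(length(dim(ad_value(x))) == 4L)
  t_gap(x)
}

#' Initialize tabular projection parameters
#'
#' Each branch (clinical, metadata) is a two-layer perceptron with a
#' normalization layer between them: `W2 gelu(BN(W1 x + b1)) + b2`. The
#' normalization uses running statistics (updated by the trainer via
#' [update_bn_stats()]) in both modes, so evaluation is deterministic.
#'
#' @param p,q input lengths of the clinical and metadata vectors.
#' @param d1,d2 output lengths of the two projections.
#' @param hidden hidden width.
#' @param dropout dropout rate applied after the activation in training.
#' @param seed integer seed.
#' @return Nested list with `$clinical` and `$metadata` branches.
#' @export
init_tabular_params <- function(p, q, d1 = 16L, d2 = 16L, hidden = 16L,
                                dropout = 0.1, seed = 1L) {
  branch <- function(n_in, n_out) list(
    W1 = matrix(rnorm(hidden * n_in, sd = sqrt(1 / n_in)), hidden, n_in),
    b1 = numeric(hidden),
    gamma = rep(1, hidden), beta = numeric(hidden),
    run_mean = numeric(hidden), run_var = rep(1, hidden),
    W2 = matrix(rnorm(n_out * hidden, sd = sqrt(1 / hidden)), n_out, hidden),
    b2 = numeric(n_out), n_in = n_in, n_out = n_out)
  with_seed(seed, list(clinical = branch(p, d1), metadata = branch(q, d2),
                       dropout = dropout))
}

#' Project a tabular vector into its compact representation
#'
#' @param x clinical or metadata vector (numeric or adnode).
#' @param which `"clinical"` or `"metadata"`.
#' @param params parameters from [init_tabular_params()] (branch weights may
#'   be adnodes during training; running stats stay numeric).
#' @param train apply dropout (draws from the current RNG stream).
#' @return Projection of configured length d1 (or d2).
#' @export
project_tabular <- function(x, which = c("clinical", "metadata"), params,
                            train = FALSE) {
  which <- match.arg(which)
  br <- params[[which]]
  n_in <- br$n_in %||% ncol(ad_value(br$W1))
  if (length(ad_value(x)) != n_in)
    stop(sprintf("project_tabular: %s vector has length %d but expected %s = %d",
                 which, length(ad_value(x)),
                 if (which == "clinical") "p" else "q", n_in))
  a <- t_add(t_matvec(br$W1, x), br$b1)
  norm <- t_add(t_mul(t_div(t_sub(a, br$run_mean), sqrt(br$run_var + 1e-5)),
                      br$gamma), br$beta)
  h <- t_gelu(norm)
  if (train && params$dropout > 0) {
    keep <- (runif(length(ad_value(h))) >= params$dropout) / (1 - params$dropout)
    h <- t_mul(h, keep)
  }
  t_add(t_matvec(br$W2, h), br$b2)
}

#' Update running normalization statistics of a tabular branch
#'
#' Exponential moving average over the batch's pre-normalization
#' activations; called by the trainer outside the gradient tape.
#'
#' @param branch one branch of [init_tabular_params()].
#' @param xs numeric matrix of input vectors (rows = samples).
#' @param momentum EMA rate.
#' @return The branch with updated `run_mean` and `run_var`.
#' @export
update_bn_stats <- function(branch, xs, momentum = 0.1) {
  a <- t(ad_value(branch$W1) %*% t(xs) + ad_value(branch$b1))
  m <- colMeans(a)
  v <- apply(a, 2, function(col) mean((col - mean(col))^2))
  branch$run_mean <- (1 - momentum) * branch$run_mean + momentum * m
  branch$run_var <- (1 - momentum) * branch$run_var + momentum * pmax(v, 1e-8)
  branch
}

#' Fuse modality blocks into the unified latent embedding
#'
#' Concatenation in fixed order (image, clinical, metadata); a missing
#' modality contributes a zero block and a FALSE presence flag.
#'
#' @param v_img length-C image descriptor (or NULL if missing).
#' @param f_clin length-d1 clinical projection (or NULL).
#' @param f_mod length-d2 metadata projection (or NULL).
#' @param dims integer vector `c(C, d1, d2)`; required when a block is
#'   missing, otherwise inferred.
#' @return A `fused_embedding`: list with `z` (length C+d1+d2), `dims`, and
#'   logical `flags` per modality.
#' @export
fuse <- function(v_img = NULL, f_clin = NULL, f_mod = NULL, dims = NULL) {
  blocks <- list(image = v_img, clinical = f_clin, metadata = f_mod)
  flags <- !vapply(blocks, is.null, logical(1))
  if (!any(flags)) stop("fuse: all modalities missing; nothing to fuse")
  if (is.null(dims))
    dims <- vapply(blocks, function(b) length(ad_value(b)), integer(1))
  stopifnot(length(dims) == 3, all(dims[flags] > 0))
  filled <- lapply(seq_along(blocks), function(i)
    if (flags[i]) blocks[[i]] else numeric(dims[i]))
  structure(list(z = t_concat(filled), dims = as.integer(dims), flags = flags),
            class = "fused_embedding")
}

#' Recover the modality blocks of a fused embedding by slicing
#' @param fe a `fused_embedding` from [fuse()].
#' @return Named list `image`, `clinical`, `metadata`.
#' @export
split_fused <- function(fe) {
  z <- ad_value(fe$z)
  off <- cumsum(c(0L, fe$dims))
  out <- lapply(1:3, function(i) z[(off[i] + 1L):off[i + 1L]])
  names(out) <- c("image", "clinical", "metadata")
  out
}
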