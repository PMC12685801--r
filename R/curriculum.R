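# Stage-1 self-supervised objectives: masked reconstruction, instance
# contrastive loss, their weighted combination, the block occlusion mask
# generator, and the momentum (EMA) parameter update.

#' Masked reconstruction loss
#'
#' `mask` marks occluded voxels with 1. The default convention is the mean
#' squared reconstruction error over occluded voxels only; the literal
#' convention (`as_printed = TRUE`) is the squared norm of
#' `recon - original * mask` over all voxels.
#'
#' @param original,recon arrays of equal shape (recon may be an adnode).
#' @param mask binary array, 1 = occluded; must occlude at least one voxel.
#' @param as_printed use the literal squared-norm convention.
#' @return Scalar loss.
#' @export
masked_recon_loss <- function(original, recon, mask, as_printed = FALSE) {
  stopifnot(identical(dim(ad_value(recon)), dim(original)),
            identical(dim(mask), dim(original)))
  if (!all(mask %in% c(0, 1))) stop("masked_recon_loss: mask must be binary")
  if (sum(mask) == 0) stop("masked_recon_loss: mask occludes nothing")
  if (as_printed)
    return(t_norm2sq(t_sub(recon, original * mask)))
  t_div(t_sum(t_mul(t_square(t_sub(recon, original)), mask)), sum(mask))
}

#' Instance contrastive loss over paired embeddings
#'
#' Temperature-scaled cross-entropy on cosine similarities: the anchor
#' `z1_i` is pulled toward its positive `z2_i` and pushed from the other
#' samples' second views. The denominator ranges over `j != i` only (it
#' excludes the positive pair), so perfectly aligned positives with
#' orthogonal negatives reach the floor `-1/tau + log(N-1)` rather than 0.
#'
#' @param z1,z2 lists (or matrix rows) of N paired embeddings, N >= 2,
#'   all nonzero.
#' @param tau temperature (> 0).
#' @return Scalar loss (mean over anchors).
#' @export
simclr_loss <- function(z1, z2, tau = 0.5) {
  l1 <- as_veclist(z1); l2 <- as_veclist(z2)
  n <- length(l1)
  stopifnot(length(l2) == n, tau > 0)
  if (n < 2) stop("simclr_loss: need at least 2 pairs (the denominator is empty otherwise)")
  terms <- lapply(seq_len(n), function(i) {
    pos <- t_div(t_cosine(l1[[i]], l2[[i]]), tau)
    negs <- lapply(setdiff(seq_len(n), i), function(j)
      t_exp(t_div(t_cosine(l1[[i]], l2[[j]]), tau)))
    t_neg(t_sub(pos, t_log(Reduce(t_add, negs))))
  })
  t_div(Reduce(t_add, terms), n)
}

#' Weighted auxiliary pretraining objective
#' @param recon reconstruction loss value.
#' @param contrastive contrastive loss value.
#' @param lambda_a,lambda_s nonnegative weights.
#' @return `lambda_a * recon + lambda_s * contrastive`.
#' @export
aux_loss <- function(recon, contrastive, lambda_a = 1, lambda_s = 1) {
  if (lambda_a < 0 || lambda_s < 0) stop("aux_loss: weights must be nonnegative")
  stopifnot(is.finite(ad_value(recon)), is.finite(ad_value(contrastive)))
  t_add(t_mul(lambda_a, recon), t_mul(lambda_s, contrastive))
}

#' Momentum (EMA) parameter update
#'
#' Elementwise `m * theta_m + (1 - m) * theta` over congruent parameter
#' collections (numeric arrays or nested lists thereof).
#'
#' @param theta_m momentum parameters.
#' @param theta online parameters.
#' @param m momentum coefficient in \[0, 1\].
#' @return Updated momentum parameters.
#' @export
momentum_update <- function(theta_m, theta, m = 0.99) {
  stopifnot(m >= 0, m <= 1)
  upd <- function(a, b) {
    if (is.list(a)) {
      stopifnot(is.list(b), length(a) == length(b))
      return(Map(upd, a, b))
    }
    if (!is.numeric(a)) return(a) # config scalars ride along unchanged
    bv <- ad_value(b)
    if (!identical(dim(a) %||% length(a), dim(bv) %||% length(bv)))
      stop("momentum_update: parameter shapes disagree")
    m * a + (1 - m) * bv
  }
  upd(theta_m, theta)
}

#' Random block occlusion mask
#'
#' Accumulates non-overlapping cubes of edge `mask_block` at random
#' positions until the occluded fraction reaches `mask_ratio` (the final
#' cube may overshoot by at most one cube volume). Draws from the given
#' seed; the same seed reproduces the same mask.
#'
#' @param shape integer vector of 3 grid dims.
#' @param mask_ratio target occluded fraction in (0, 1).
#' @param mask_block cube edge length (must fit inside the grid).
#' @param seed integer seed.
#' @return Binary array, 1 = occluded.
#' @export
make_mask <- function(shape, mask_ratio = 0.5, mask_block = 4L, seed = 1L) {
  stopifnot(mask_ratio > 0, mask_ratio < 1)
  shape <- as.integer(shape)
  if (any(mask_block > shape))
    stop(sprintf("make_mask: block edge %d exceeds grid (%s)",
                 mask_block, paste(shape, collapse = "x")))
  mask <- array(0, dim = shape)
  total <- prod(shape)
  with_seed(seed, {
    tries <- 0L
    while (sum(mask) / total < mask_ratio && tries < 10000L) {
      o <- vapply(shape, function(n) sample.int(n - mask_block + 1L, 1L), integer(1))
      blk <- mask[o[1]:(o[1] + mask_block - 1L), o[2]:(o[2] + mask_block - 1L),
                  o[3]:(o[3] + mask_block - 1L)]
      tries <- tries + 1L
      if (any(blk == 1)) next # keep cubes non-overlapping
      mask[o[1]:(o[1] + mask_block - 1L), o[2]:(o[2] + mask_block - 1L),
           o[3]:(o[3] + mask_block - 1L)] <- 1
    }
  })
  mask
}

#' Initialize the reconstruction decoder
#'
#' A light decoder discarded after pretraining: nearest-neighbour 2x
#' upsampling of the encoder features followed by one smoothing convolution
#' down to a single intensity channel.
#'
#' @param channels encoder channel count C.
#' @param kernel odd kernel edge.
#' @param seed integer seed.
#' @return Parameter list with `dec_w`, `dec_b`.
#' @export
init_decoder_params <- function(channels, kernel = 3L, seed = 1L) {
  with_seed(seed, list(
    dec_w = array(rnorm(kernel^3 * channels, sd = sqrt(2 / (kernel^3 * channels))),
                  dim = c(kernel, kernel, kernel, channels, 1L)),
    dec_b = 0))
}

#' Decode encoder features back to a volume
#' @param feat `(H', W', D', C)` feature tensor (or adnode).
#' @param params decoder parameters from [init_decoder_params()].
#' @return Reconstructed `(2H', 2W', 2D')` volume.
#' @export
decode_volume <- function(feat, params) {
  k <- dim(ad_value(params$dec_w))[1]
  up <- t_upsample2(feat)
  y <- t_conv3d(up, params$dec_w, stride = 1L, pad = (k - 1L) %/% 2L)
  y <- t_add(y, params$dec_b)
  d <- dim(ad_value(y))
  if (is_adnode(y)) {
    yv <- ad_value(y); dim(yv) <- d[1:3]
    ad_make(yv, list(y), function(g) {
      dim(g) <- d
      list(g)
    })
  } else array(y, dim = d[1:3])
}
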