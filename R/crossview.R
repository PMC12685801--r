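# Cross-view consistency between paired acquisitions of the same anatomy:
# plain embedding consistency, a view-aware contrastive loss, and a
# consistency variant that spatially aligns the second view with a small
# affine module before encoding.

#' Cross-view consistency loss
#'
#' Mean over pairs of the squared embedding distance
#' `|| z_a_i - z_b_i ||^2`.
#'
#' @param za,zb paired embeddings (matrix rows or lists), equal counts.
#' @return Scalar loss.
#' @export
consistency_loss <- function(za, zb) {
  la <- as_veclist(za); lb <- as_veclist(zb)
  if (length(la) != length(lb))
    stop("consistency_loss: view batches have different counts")
  terms <- Map(function(a, b) t_norm2sq(t_sub(a, b)), la, lb)
  t_div(Reduce(t_add, terms), length(terms))
}

#' View-aware contrastive loss
#'
#' Same construction as [simclr_loss()] with the two views as the pair
#' sets: anchors from view a, positives/negatives from view b, denominator
#' over `j != i`.
#'
#' @param za,zb paired embeddings, N >= 2.
#' @param tau temperature (> 0).
#' @return Scalar loss.
#' @export
view_contrastive_loss <- function(za, zb, tau = 0.5) simclr_loss(za, zb, tau)

#' Initialize the affine alignment module
#'
#' A per-pair affine transform (12 parameters: 3 x 4 matrix in voxel
#' coordinates) predicted by a linear head on coarse 2x2x2 block means of
#' the two raw volumes. The head starts at zero, so the module starts at
#' the identity transform.
#'
#' @param seed integer seed (kept for interface symmetry; init is
#'   deterministic zeros).
#' @return Parameter list with `W` (12 x 16) and `b` (12).
#' @export
init_aligner_params <- function(seed = 1L) {
  list(W = matrix(0, 12, 16), b = numeric(12))
}

# coarse 2x2x2 block means of a volume -> length-8 summary
coarse_pool8 <- function(vol) {
  d <- dim(vol)
  h <- d %/% 2
  v <- numeric(8)
  i <- 0L
  for (dz in 0:1) for (dy in 0:1) for (dx in 0:1) {
    i <- i + 1L
    v[i] <- mean(vol[(dx * h[1] + 1):((dx + 1) * h[1]),
                     (dy * h[2] + 1):((dy + 1) * h[2]),
                     (dz * h[3] + 1):((dz + 1) * h[3])])
  }
  v
}

#' Predict the per-pair affine parameters
#' @param xa,xb raw paired volumes (numeric arrays).
#' @param params aligner parameters ([init_aligner_params()]; may hold
#'   adnodes during training).
#' @return Length-12 vector: the row-major offsets of the 3 x 4 transform
#'   added to the identity.
#' @export
predict_affine <- function(xa, xb, params) {
  u <- c(coarse_pool8(ad_value(xa)), coarse_pool8(ad_value(xb)))
  t_add(t_matvec(params$W, u), params$b)
}

# differentiable affine resampling: theta (length-12 node, offsets from the
# identity) warps `vol` (numeric) by trilinear interpolation. Source
# coordinates are A %*% (x - c) + c + t around the grid centre c.
t_affine_warp <- function(vol, theta) {
  vv <- ad_value(vol)
  d <- dim(vv)
  cen <- (d + 1) / 2
  ax <- seq_len(d[1]); ay <- seq_len(d[2]); az <- seq_len(d[3])
  gx <- rep(ax, times = d[2] * d[3]) - cen[1]
  gy <- rep(rep(ay, each = d[1]), times = d[3]) - cen[2]
  gz <- rep(az, each = d[1] * d[2]) - cen[3]
  compute <- function(th) {
    A <- matrix(th[1:9], 3, 3, byrow = TRUE) + diag(3)
    t3 <- th[10:12]
    sx <- A[1, 1] * gx + A[1, 2] * gy + A[1, 3] * gz + cen[1] + t3[1]
    sy <- A[2, 1] * gx + A[2, 2] * gy + A[2, 3] * gz + cen[2] + t3[2]
    sz <- A[3, 1] * gx + A[3, 2] * gy + A[3, 3] * gz + cen[3] + t3[3]
    f <- function(s, n) pmin(pmax(s, 1), n)
    sx <- f(sx, d[1]); sy <- f(sy, d[2]); sz <- f(sz, d[3])
    x0 <- pmin(floor(sx), d[1] - 1); y0 <- pmin(floor(sy), d[2] - 1)
    z0 <- pmin(floor(sz), d[3] - 1)
    fx <- sx - x0; fy <- sy - y0; fz <- sz - z0
    at <- function(ix, iy, iz) vv[cbind(ix, iy, iz)]
    c000 <- at(x0, y0, z0); c100 <- at(x0 + 1, y0, z0)
    c010 <- at(x0, y0 + 1, z0); c110 <- at(x0 + 1, y0 + 1, z0)
    c001 <- at(x0, y0, z0 + 1); c101 <- at(x0 + 1, y0, z0 + 1)
    c011 <- at(x0, y0 + 1, z0 + 1); c111 <- at(x0 + 1, y0 + 1, z0 + 1)
    w000 <- (1 - fx) * (1 - fy) * (1 - fz); w100 <- fx * (1 - fy) * (1 - fz)
    w010 <- (1 - fx) * fy * (1 - fz); w110 <- fx * fy * (1 - fz)
    w001 <- (1 - fx) * (1 - fy) * fz; w101 <- fx * (1 - fy) * fz
    w011 <- (1 - fx) * fy * fz; w111 <- fx * fy * fz
    out <- c000 * w000 + c100 * w100 + c010 * w010 + c110 * w110 +
      c001 * w001 + c101 * w101 + c011 * w011 + c111 * w111
    # d(out)/d(source coordinate), for the chain rule to theta
    dux <- (c100 - c000) * (1 - fy) * (1 - fz) + (c110 - c010) * fy * (1 - fz) +
      (c101 - c001) * (1 - fy) * fz + (c111 - c011) * fy * fz
    duy <- (c010 - c000) * (1 - fx) * (1 - fz) + (c110 - c100) * fx * (1 - fz) +
      (c011 - c001) * (1 - fx) * fz + (c111 - c101) * fx * fz
    duz <- (c001 - c000) * (1 - fx) * (1 - fy) + (c101 - c100) * fx * (1 - fy) +
      (c011 - c010) * (1 - fx) * fy + (c111 - c110) * fx * fy
    list(out = array(out, dim = d), dux = dux, duy = duy, duz = duz)
  }
  th <- ad_value(theta)
  res <- compute(th)
  ad_make(res$out, list(theta), function(g) {
    gv <- as.numeric(g)
    gx_ <- gv * res$dux; gy_ <- gv * res$duy; gz_ <- gv * res$duz
    dth <- c(sum(gx_ * gx), sum(gx_ * gy), sum(gx_ * gz),
             sum(gy_ * gx), sum(gy_ * gy), sum(gy_ * gz),
             sum(gz_ * gx), sum(gz_ * gy), sum(gz_ * gz),
             sum(gx_), sum(gy_), sum(gz_))
    list(dth)
  })
}

#' Aligned cross-view consistency loss
#'
#' Mean over pairs of `|| phi(x_a) - phi(A(x_b)) ||^2` where `phi` encodes
#' a volume to its pooled descriptor and `A` is the affine alignment module
#' (identity when `aligner` is NULL, in which case this reduces to
#' [consistency_loss()] on the encoded raw pair).
#'
#' @param xa,xb lists of paired raw volumes.
#' @param encoder_params,encoder_cfg shared encoder (see
#'   [encode_region()]).
#' @param aligner NULL for identity, or parameters from
#'   [init_aligner_params()].
#' @return Scalar loss.
#' @export
aligned_consistency_loss <- function(xa, xb, encoder_params, encoder_cfg,
                                     aligner = NULL) {
  if (!is.list(xa)) xa <- list(xa)
  if (!is.list(xb)) xb <- list(xb)
  stopifnot(length(xa) == length(xb))
  phi <- function(v) t_gap(encode_region(v, encoder_params, encoder_cfg))
  terms <- Map(function(a, b) {
    bb <- if (is.null(aligner)) b
    else t_affine_warp(b, predict_affine(a, b, aligner))
    t_norm2sq(t_sub(phi(a), phi(bb)))
  }, xa, xb)
  t_div(Reduce(t_add, terms), length(terms))
}
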