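# Structural regularizers and heads: hierarchical consistency, center loss,
# linear maximum mean discrepancy, mask-guided total variation, and the
# pathology-severity regression loss. All reductions are batch means, so
# the lambda weights are batch-size-free.

# normalize batch input: numeric matrix (rows = samples), list of vectors /
# adnodes, or a single vector -> list of vectors
as_veclist <- function(x) {
  if (is.list(x) && !is_adnode(x)) return(x)
  if (is_adnode(x)) return(list(x))
  if (is.matrix(x)) return(lapply(seq_len(nrow(x)), function(i) x[i, ]))
  list(x)
}

#' Simplex reparametrization of learned region importance weights
#'
#' The K importance weights used by [hierarchical_consistency()] are trained
#' as free logits and mapped through a softmax, so they stay nonnegative and
#' sum to one by construction.
#'
#' @param logits length-K free parameter vector (numeric or adnode).
#' @return Length-K simplex weights.
#' @export
simplex_weights <- function(logits) t_softmax(logits)

#' Hierarchical consistency loss
#'
#' Penalizes the distance between the global embedding and the importance-
#' weighted combination of regional embeddings:
#' `mean_i || z_i - sum_k alpha_k z_ik ||^2`.
#'
#' @param global batch of global embeddings (matrix rows, list, or single
#'   vector).
#' @param regional for each sample, a list (or K x d matrix) of K regional
#'   embeddings; a single sample may be passed directly.
#' @param alpha length-K simplex weights (see [simplex_weights()]).
#' @return Scalar loss (batch mean).
#' @export
hierarchical_consistency <- function(global, regional, alpha) {
  gl <- as_veclist(global)
  if (is.matrix(regional) || (is.list(regional) && length(gl) == 1L &&
                              !is.list(regional[[1]])))
    regional <- list(regional)
  stopifnot(length(gl) == length(regional))
  av <- if (is_adnode(alpha)) lapply(seq_along(ad_value(alpha)),
                                     function(k) t_index(alpha, k))
  else as.list(ad_value(alpha))
  terms <- Map(function(z, zk) {
    zk <- as_veclist(if (is.matrix(zk)) zk else zk)
    if (length(zk) != length(av))
      stop("hierarchical_consistency: number of regional embeddings must match alpha")
    if (length(ad_value(zk[[1]])) != length(ad_value(z)))
      stop("hierarchical_consistency: regional and global embedding dims disagree")
    comb <- Reduce(t_add, Map(function(a, v) t_mul(a, v), av, zk))
    t_norm2sq(t_sub(z, comb))
  }, gl, regional)
  t_div(Reduce(t_add, terms), length(terms))
}

#' Class-center loss
#'
#' `mean_i || z_i - c_{y_i} ||^2` with one centroid per class.
#'
#' @param z batch embeddings (matrix rows or list of vectors/adnodes).
#' @param labels integer class labels (0-based or any values present in
#'   `centroids`' names).
#' @param centroids named list (or matrix rows named by class) of centroid
#'   vectors.
#' @return Scalar loss (batch mean).
#' @export
center_loss <- function(z, labels, centroids) {
  zl <- as_veclist(z)
  stopifnot(length(zl) == length(labels))
  if (is.matrix(centroids))
    centroids <- stats::setNames(lapply(seq_len(nrow(centroids)), function(i) centroids[i, ]),
                                 rownames(centroids))
  terms <- Map(function(zi, y) {
    key <- as.character(y)
    if (is.null(centroids[[key]]))
      stop(sprintf("center_loss: no centroid for label '%s'", key))
    t_norm2sq(t_sub(zi, centroids[[key]]))
  }, zl, labels)
  t_div(Reduce(t_add, terms), length(terms))
}

#' Update class centroids by exponential moving average
#'
#' Each class centroid moves toward the mean of the batch embeddings of
#' that class at the given rate.
#'
#' @param centroids named list of centroid vectors.
#' @param z numeric matrix of batch embeddings (rows = samples).
#' @param labels class labels aligned with rows.
#' @param rate EMA rate (default 0.1).
#' @return Updated centroid list.
#' @export
update_centroids <- function(centroids, z, labels, rate = 0.1) {
  for (key in unique(as.character(labels))) {
    m <- colMeans(z[as.character(labels) == key, , drop = FALSE])
    centroids[[key]] <- if (is.null(centroids[[key]])) m
    else (1 - rate) * centroids[[key]] + rate * m
  }
  centroids
}

#' Linear maximum mean discrepancy between two cohorts
#'
#' Squared Euclidean distance between the two batch mean embeddings.
#'
#' @param za,zb embeddings of cohorts A and B (matrix rows or lists).
#' @return Scalar discrepancy.
#' @export
mmd_linear <- function(za, zb) {
  la <- as_veclist(za); lb <- as_veclist(zb)
  if (length(la) == 0 || length(lb) == 0)
    stop("mmd_linear: both cohorts must be nonempty")
  mu_a <- t_div(Reduce(t_add, la), length(la))
  mu_b <- t_div(Reduce(t_add, lb), length(lb))
  t_norm2sq(t_sub(mu_a, mu_b))
}

#' Mask-guided total-variation regularizer
#'
#' L1 norm of forward finite differences of each regional feature map along
#' the three spatial axes, counting only voxel pairs that both lie inside
#' the region mask. Feature maps may carry a trailing channel dimension.
#'
#' @param fmaps list of K regional feature maps (3D or 4D arrays/adnodes).
#' @param masks list of K binary masks on the feature grid.
#' @return Scalar penalty (sum over regions and axes).
#' @export
mask_tv <- function(fmaps, masks) {
  stopifnot(length(fmaps) == length(masks))
  diff_axis <- function(x, m, axis) {
    d <- dim(ad_value(x))
    n <- d[axis]
    if (n < 2) return(NULL)
    idx_a <- idx_b <- lapply(d, seq_len)
    idx_a[[axis]] <- 1:(n - 1)
    idx_b[[axis]] <- 2:n
    pick <- function(arr, idx) do.call(`[`, c(list(arr), idx, list(drop = FALSE)))
    # pair weight: both voxels inside the mask
    ma <- do.call(`[`, c(list(m), idx_a[seq_len(length(dim(m)))], list(drop = FALSE)))
    mb <- do.call(`[`, c(list(m), idx_b[seq_len(length(dim(m)))], list(drop = FALSE)))
    w <- ma * mb
    if (length(d) == 4L && length(dim(m)) == 3L) w <- array(w, dim = c(dim(w), d[4]))
    if (sum(w) == 0) return(NULL)
    xa <- if (is_adnode(x)) ad_subset(x, idx_a) else pick(x, idx_a)
    xb <- if (is_adnode(x)) ad_subset(x, idx_b) else pick(x, idx_b)
    t_sum(t_mul(t_abs(t_sub(xb, xa)), w))
  }
  terms <- list()
  for (k in seq_along(fmaps)) {
    for (axis in 1:3) {
      tk <- diff_axis(fmaps[[k]], masks[[k]], axis)
      if (!is.null(tk)) terms <- c(terms, list(tk))
    }
  }
  if (length(terms) == 0) return(0)
  Reduce(t_add, terms)
}

# differentiable array subsetting (list of index vectors per dimension)
ad_subset <- function(x, idx) {
  xv <- ad_value(x)
  y <- do.call(`[`, c(list(xv), idx, list(drop = FALSE)))
  ad_make(y, list(x), function(g) {
    if (is.null(dim(g))) dim(g) <- dim(y)
    gr <- zeros_like(xv)
    ref <- do.call(`[`, c(list(gr), idx, list(drop = FALSE)))
    gr_idx <- do.call(`[<-`, c(list(gr), idx, list(value = ref + g)))
    list(gr_idx)
  })
}

#' Pathology severity regression loss
#'
#' Mean squared error between the observed severity scores and the head's
#' predictions `psi(z)`.
#'
#' @param s numeric severity scores.
#' @param pred predicted scores (numeric or adnodes), same length.
#' @return Scalar MSE.
#' @export
patho_regression_loss <- function(s, pred) {
  pl <- if (is.list(pred)) pred
  else if (is_adnode(pred)) lapply(seq_along(ad_value(pred)), function(i) t_index(pred, i))
  else as.list(pred)
  stopifnot(length(s) == length(pl), all(is.finite(s)))
  terms <- Map(function(si, pi) t_square(t_sub(pi, si)), s, pl)
  t_div(Reduce(t_add, terms), length(terms))
}

#' Linear severity head
#' @param z embedding vector (or adnode).
#' @param psi list with weight vector `w` and scalar `b`.
#' @return Scalar predicted severity.
#' @export
severity_head <- function(z, psi) t_add(t_dot(psi$w, z), psi$b)
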