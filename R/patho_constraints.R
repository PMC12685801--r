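# Knowledge-guided soft constraints: ordinal monotonicity of severity
# predictions, bilateral lung symmetry, label co-occurrence, and zone
# attention. Each is a batch-mean penalty.

#' Ordinal monotonicity (ranking hinge) loss
#'
#' Over all ordered pairs with `y_i > y_j`, penalizes
#' `max(0, s_j - s_i + delta)`: the prediction for the more severe case
#' must exceed the other by at least the margin. Normalized by the number
#' of ordered pairs; 0 when no ordered pairs exist.
#'
#' @param scores predicted severity scores (numeric vector or list of
#'   scalars/adnodes).
#' @param labels ordinal ground-truth labels.
#' @param delta positive margin.
#' @return Scalar loss.
#' @export
monotonicity_loss <- function(scores, labels, delta = 0.1) {
  stopifnot(delta > 0)
  sl <- if (is.list(scores)) scores
  else if (is_adnode(scores)) lapply(seq_along(ad_value(scores)), function(i) t_index(scores, i))
  else as.list(scores)
  stopifnot(length(sl) == length(labels))
  n <- length(sl)
  terms <- list()
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (labels[i] > labels[j])
      terms <- c(terms, list(t_relu(t_add(t_sub(sl[[j]], sl[[i]]), delta))))
  }
  if (length(terms) == 0) return(0)
  t_div(Reduce(t_add, terms), length(terms))
}

#' Bilateral symmetry loss
#'
#' Batch mean of the squared distance between the left-lung descriptor and
#' the transformed right-lung descriptor, `||f_L - T f_R||^2`. `T` is a
#' learnable linear map initialized at the identity (the spatial mirror is
#' implicit at the pooled-descriptor level). With `weights`, per-sample
#' contributions are scaled (selective symmetry enforcement for focal
#' asymmetry).
#'
#' @param f_left,f_right descriptors (single vectors, matrix rows, or lists
#'   of vectors/adnodes).
#' @param Tmat d x d transform matrix (numeric or adnode); identity by
#'   default.
#' @param weights optional per-sample nonnegative weights.
#' @return Scalar loss (batch mean).
#' @export
symmetry_loss <- function(f_left, f_right, Tmat = NULL, weights = NULL) {
  ll <- as_veclist(f_left); lr <- as_veclist(f_right)
  stopifnot(length(ll) == length(lr))
  d <- length(ad_value(ll[[1]]))
  if (is.null(Tmat)) Tmat <- diag(d)
  if (any(dim(ad_value(Tmat)) != c(d, length(ad_value(lr[[1]])))))
    stop("symmetry_loss: transform shape incompatible with descriptors")
  terms <- Map(function(fl, fr) {
    if (length(ad_value(fl)) != d) stop("symmetry_loss: descriptor shapes disagree")
    t_norm2sq(t_sub(fl, t_matvec(Tmat, fr)))
  }, ll, lr)
  if (!is.null(weights)) {
    stopifnot(length(weights) == length(terms), all(weights >= 0))
    terms <- Map(function(tm, w) t_mul(w, tm), terms, as.list(weights))
  }
  t_div(Reduce(t_add, terms), length(terms))
}

#' Label co-occurrence consistency loss
#'
#' `mean_i || y_hat_i - C y_hat_i ||^2`: predicted label distributions
#' should be near fixed points of the co-occurrence operator.
#'
#' @param preds predicted label vectors (matrix rows or list).
#' @param C row-normalized nonnegative co-occurrence matrix.
#' @return Scalar loss (batch mean).
#' @export
cooccurrence_loss <- function(preds, C) {
  validate_cooccurrence(C)
  pl <- as_veclist(preds)
  terms <- lapply(pl, function(p) t_norm2sq(t_sub(p, t_matvec(C, p))))
  t_div(Reduce(t_add, terms), length(terms))
}

validate_cooccurrence <- function(C) {
  if (!is.matrix(ad_value(C)) || nrow(ad_value(C)) != ncol(ad_value(C)))
    stop("co-occurrence matrix must be square")
  Cv <- ad_value(C)
  if (any(Cv < 0)) stop("co-occurrence matrix must be nonnegative")
  if (any(abs(rowSums(Cv) - 1) > 1e-6))
    stop("co-occurrence matrix rows must sum to 1 (within 1e-6)")
  invisible(TRUE)
}

#' Estimate the co-occurrence matrix from a binary label table
#'
#' `C[i, j] = count(i and j co-occur) / count(i occurs)`, rows then
#' renormalized to sum to one.
#'
#' @param labels n_samples x n_labels binary matrix.
#' @return Row-normalized co-occurrence matrix.
#' @export
estimate_cooccurrence <- function(labels) {
  L <- as.matrix(labels)
  occ <- colSums(L)
  if (any(occ == 0)) {
    bad <- which(occ == 0)
    nm <- colnames(L)[bad] %||% as.character(bad)
    stop(sprintf("estimate_cooccurrence: label(s) %s never occur",
                 paste(nm, collapse = ", ")))
  }
  C <- crossprod(L) / occ # row i divided by count(i occurs)
  C / rowSums(C)
}

#' Zone attention loss
#'
#' `|| H * Z - H ||^2`, i.e. the squared heatmap mass outside the zone
#' mask, averaged over the batch.
#'
#' @param heatmaps a single array/adnode or a list of them.
#' @param zone binary zone mask with the heatmap's dimensions.
#' @return Scalar loss (batch mean).
#' @export
zone_loss <- function(heatmaps, zone) {
  if (!is.list(heatmaps)) heatmaps <- list(heatmaps)
  stopifnot(all(zone %in% c(0, 1)))
  terms <- lapply(heatmaps, function(H) {
    stopifnot(identical(dim(ad_value(H)), dim(zone)))
    t_norm2sq(t_sub(t_mul(H, zone), H))
  })
  t_div(Reduce(t_add, terms), length(terms))
}

#' Per-sample selective symmetry weights
#'
#' `sigma(-asymmetry)`: strongly asymmetric samples (e.g. unilateral
#' lesions) are down-weighted in the symmetry constraint.
#'
#' @param asymmetry numeric vector of per-sample asymmetry scores.
#' @return Weights in (0, 1).
#' @export
selective_symmetry_weights <- function(asymmetry) 1 / (1 + exp(asymmetry))
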