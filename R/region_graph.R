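# Graph-attention message passing over lobe nodes. The graph is small
# (K nodes, K ~ 5) so attention is computed per neighbourhood with exact
# softmax normalization; multi-head outputs are averaged by default.

#' Build the lobe adjacency
#'
#' Scheme `"lobar"` connects lobes within each lung in a superior-inferior
#' chain and adds two inter-lung edges (between the two upper lobes and
#' between the two lower lobes), giving 5 undirected edges at K = 5.
#' `"full"` is the complete graph; `"custom"` takes a user adjacency.
#'
#' @param K number of regions.
#' @param scheme `"lobar"`, `"full"`, or `"custom"`.
#' @param adjacency for `"custom"`: a symmetric K x K 0/1 matrix, or a
#'   directed edge list (2-column matrix, 1-based) that must contain both
#'   directions of every edge.
#' @return A `region_adjacency` object: list with `edges` (m x 2 matrix of
#'   undirected edges, i < j) and `K`.
#' @export
build_adjacency <- function(K, scheme = c("lobar", "full", "custom"),
                            adjacency = NULL) {
  scheme <- match.arg(scheme)
  K <- as.integer(K)
  stopifnot(K >= 1)
  edges <- switch(scheme,
    lobar = {
      n_left <- max(0L, min(K - 1L, as.integer(round(2 * K / 5))))
      n_right <- K - n_left
      e <- NULL
      if (n_right > 1) e <- rbind(e, cbind(1:(n_right - 1), 2:n_right))
      if (n_left > 1) e <- rbind(e, cbind(n_right + 1:(n_left - 1), n_right + 2:n_left))
      if (n_left >= 1) {
        e <- rbind(e, c(1L, n_right + 1L))          # upper-lobe bridge
        e <- rbind(e, c(n_right, K))                 # lower-lobe bridge
      }
      e
    },
    full = if (K >= 2) t(utils::combn(K, 2)) else NULL,
    custom = {
      if (is.null(adjacency)) stop("build_adjacency: custom scheme needs an adjacency")
      if (is.matrix(adjacency) && nrow(adjacency) == K && ncol(adjacency) == K) {
        if (!isTRUE(all.equal(adjacency, t(adjacency))))
          stop("build_adjacency: custom adjacency matrix must be symmetric")
        w <- which(adjacency != 0 & upper.tri(adjacency), arr.ind = TRUE)
        unname(cbind(w[, 1], w[, 2]))
      } else {
        el <- matrix(as.integer(adjacency), ncol = 2)
        if (any(el < 1) || any(el > K))
          stop(sprintf("build_adjacency: custom adjacency references a node outside 1..%d", K))
        key <- paste(el[, 1], el[, 2])
        rkey <- paste(el[, 2], el[, 1])
        if (!all(rkey %in% key))
          stop("build_adjacency: custom edge list is asymmetric; every edge needs both directions")
        und <- unique(t(apply(el[el[, 1] != el[, 2], , drop = FALSE], 1, sort)))
        if (nrow(und) == 0) NULL else und
      }
    })
  if (!is.null(edges) && NROW(edges) > 0) {
    edges <- matrix(as.integer(edges), ncol = 2)
    edges <- unique(t(apply(edges, 1, sort)))
    edges <- edges[edges[, 1] != edges[, 2], , drop = FALSE]
    edges <- edges[!duplicated(paste(edges[, 1], edges[, 2])), , drop = FALSE]
    if (any(edges > K)) stop("build_adjacency: edge references node beyond K")
  } else edges <- matrix(integer(0), ncol = 2)
  structure(list(edges = edges, K = K, scheme = scheme), class = "region_adjacency")
}

# neighbours of node k; isolated nodes get a self-loop so the message sum
# is always defined
adj_neighbors <- function(adj, k) {
  e <- adj$edges
  nb <- c(e[e[, 2] == k, 1], e[e[, 1] == k, 2])
  if (length(nb) == 0) k else sort(nb)
}

#' Initialize graph-attention parameters
#'
#' @param channels input node feature length C.
#' @param d output embedding length per node.
#' @param da attention projection width.
#' @param heads number of attention heads.
#' @param combine `"average"` or `"concat"` head combination.
#' @param seed integer seed.
#' @return Parameter list with per-head `Wq`, `Wk`, `a`, `Wmsg` and shared
#'   residual transform `rho_W`, `rho_b`, `Wres`.
#' @export
init_graph_params <- function(channels, d = channels, da = 8L, heads = 2L,
                              combine = c("average", "concat"), seed = 1L) {
  combine <- match.arg(combine)
  msg_dim <- if (combine == "concat") d * heads else d
  with_seed(seed, {
    p <- list(heads = as.integer(heads), combine = combine, d = as.integer(d))
    for (h in seq_len(heads)) {
      s <- sqrt(1 / channels)
      p[[sprintf("h%d_Wq", h)]] <- matrix(rnorm(da * channels, sd = s), da, channels)
      p[[sprintf("h%d_Wk", h)]] <- matrix(rnorm(da * channels, sd = s), da, channels)
      p[[sprintf("h%d_a", h)]] <- rnorm(2 * da, sd = sqrt(1 / (2 * da)))
      p[[sprintf("h%d_Wmsg", h)]] <- matrix(rnorm(d * channels, sd = s), d, channels)
    }
    p$rho_W <- matrix(rnorm(d * msg_dim, sd = sqrt(1 / msg_dim)), d, msg_dim)
    p$rho_b <- numeric(d)
    p$Wres <- matrix(rnorm(d * channels, sd = sqrt(1 / channels)), d, channels)
    p
  })
}

# attention weights of one head over the neighbourhood of node k:
# softmax_j of a' LeakyReLU([Wq h_j ; Wk h_k])
gat_head_weights <- function(hs, adj, params, head, k, slope = 0.2) {
  nb <- adj_neighbors(adj, k)
  Wq <- params[[sprintf("h%d_Wq", head)]]
  Wk <- params[[sprintf("h%d_Wk", head)]]
  a <- params[[sprintf("h%d_a", head)]]
  tgt <- t_matvec(Wk, hs[[k]])
  logits <- t_concat(lapply(nb, function(j)
    t_dot(a, t_leaky_relu(t_concat(list(t_matvec(Wq, hs[[j]]), tgt)), slope))))
  list(nb = nb, eta = t_softmax(logits))
}

#' Edge attention weights over every neighbourhood
#'
#' Additive graph attention: the weight of node j's message to node k is the
#' softmax over N(k) of `a' LeakyReLU([Wq h_j ; Wk h_k])`, so weights into
#' each node sum to one.
#'
#' @param hs list of K node feature vectors (length C).
#' @param adj a [build_adjacency()] object.
#' @param params graph parameters from [init_graph_params()].
#' @param head which attention head to evaluate.
#' @param slope LeakyReLU negative slope.
#' @return K x K matrix `eta` with `eta[j, k]` the weight of j's message to
#'   k (zero off the neighbourhood); columns sum to 1 over N(k).
#' @export
edge_attention <- function(hs, adj, params, head = 1L, slope = 0.2) {
  if (is.matrix(hs)) hs <- lapply(seq_len(nrow(hs)), function(i) hs[i, ])
  K <- adj$K
  eta <- matrix(0, K, K)
  for (k in seq_len(K)) {
    hw <- gat_head_weights(hs, adj, params, head, k, slope)
    eta[hw$nb, k] <- ad_value(hw$eta)
  }
  eta
}

#' Graph-attention message passing
#'
#' `h'_k = GELU(rho_W m_k + rho_b) + Wres h_k` where `m_k` is the
#' attention-weighted sum of projected neighbour messages
#' `sum_j eta(j,k) Wmsg h_j`, with multi-head outputs averaged (or
#' concatenated before the residual transform).
#'
#' @param hs list of K node feature vectors (numeric or adnodes).
#' @param adj a [build_adjacency()] object.
#' @param params graph parameters from [init_graph_params()].
#' @param slope LeakyReLU negative slope for the attention logits.
#' @return List of K refined embeddings of length `params$d`.
#' @export
message_pass <- function(hs, adj, params, slope = 0.2) {
  if (is.matrix(hs)) hs <- lapply(seq_len(nrow(hs)), function(i) hs[i, ])
  K <- adj$K
  lapply(seq_len(K), function(k) {
    head_msgs <- lapply(seq_len(params$heads), function(h) {
      hw <- gat_head_weights(hs, adj, params, h, k, slope)
      Wmsg <- params[[sprintf("h%d_Wmsg", h)]]
      terms <- Map(function(j, pos) t_mul(t_index(hw$eta, pos), t_matvec(Wmsg, hs[[j]])),
                   hw$nb, seq_along(hw$nb))
      Reduce(t_add, terms)
    })
    msg <- if (params$combine == "concat") t_concat(head_msgs)
    else t_div(Reduce(t_add, head_msgs), length(head_msgs))
    t_add(t_gelu(t_add(t_matvec(params$rho_W, msg), params$rho_b)),
          t_matvec(params$Wres, hs[[k]]))
  })
}

#' Graph smoothness regularizer
#'
#' Sum over undirected edges of the squared distance between the refined
#' embeddings of the two endpoints; each edge counted once.
#'
#' @param hs list of K refined embeddings.
#' @param adj a [build_adjacency()] object (or an m x 2 edge matrix).
#' @return Scalar penalty (0 with a warning for an empty edge set).
#' @export
graph_smoothness <- function(hs, adj) {
  if (is.matrix(hs)) hs <- lapply(seq_len(nrow(hs)), function(i) hs[i, ])
  edges <- if (inherits(adj, "region_adjacency")) adj$edges else adj
  if (nrow(edges) == 0) {
    warning("graph_smoothness: empty edge set; returning 0")
    return(0)
  }
  terms <- lapply(seq_len(nrow(edges)), function(e)
    t_norm2sq(t_sub(hs[[edges[e, 1]]], hs[[edges[e, 2]]])))
  Reduce(t_add, terms)
}

#' Concatenate refined node embeddings in region order
#' @param hs list of K embeddings of length d.
#' @return Vector of length K*d.
#' @export
concat_descriptor <- function(hs) {
  if (is.matrix(hs)) hs <- lapply(seq_len(nrow(hs)), function(i) hs[i, ])
  t_concat(hs)
}

#' Empirical inter-region potential matrix
#'
#' `Theta[i, j]` is the dataset mean of the cosine similarity between the
#' region-i and region-j embeddings of each sample; symmetric with unit
#' diagonal. Exposed as a diagnostic report.
#'
#' @param embeddings list over samples, each a K x C matrix (or list of K
#'   vectors) of region embeddings.
#' @return K x K symmetric matrix with unit diagonal. Sample pairs where
#'   either embedding has zero norm are skipped with a warning.
#' @export
potential_matrix <- function(embeddings) {
  stopifnot(length(embeddings) >= 1)
  as_mat <- function(e) if (is.matrix(e)) e else do.call(rbind, e)
  K <- nrow(as_mat(embeddings[[1]]))
  acc <- matrix(0, K, K)
  cnt <- matrix(0, K, K)
  skipped <- FALSE
  for (e in embeddings) {
    m <- as_mat(e)
    nr <- sqrt(rowSums(m^2))
    for (i in seq_len(K)) for (j in seq_len(K)) {
      if (nr[i] == 0 || nr[j] == 0) { skipped <- TRUE; next }
      acc[i, j] <- acc[i, j] + sum(m[i, ] * m[j, ]) / (nr[i] * nr[j])
      cnt[i, j] <- cnt[i, j] + 1
    }
  }
  if (skipped) warning("potential_matrix: zero-norm embeddings skipped")
  theta <- ifelse(cnt > 0, acc / pmax(cnt, 1), NA_real_)
  theta <- (theta + t(theta)) / 2
  diag(theta) <- 1
  theta
}
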