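#' @useDynLib lobenet, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats pnorm dnorm rnorm runif sd quantile
NULL

# ---------------------------------------------------------------------------
# Reverse-mode automatic differentiation on plain R arrays.
#
# Every t_* operator accepts either numeric arrays or `adnode` objects and
# returns a numeric value when all inputs are numeric, so the same forward
# code serves both plain evaluation and gradient-based training. An adnode is
# an environment holding `value`, the list of its inputs, and a backward
# closure mapping the upstream gradient to gradients for each input.
# ---------------------------------------------------------------------------

is_adnode <- function(x) inherits(x, "adnode")

#' Numeric value of a node or plain numeric
#' @param x an `adnode` or numeric array.
#' @return The underlying numeric value.
#' @export
ad_value <- function(x) if (is_adnode(x)) x$value else x

#' Create a trainable parameter node
#' @param value numeric array holding the initial parameter value.
#' @return An `adnode` whose gradient is populated by [ad_backward()].
#' @export
ad_param <- function(value) {
  e <- new.env(parent = emptyenv())
  e$value <- value
  e$grad <- NULL
  e$inputs <- NULL
  e$backward <- NULL
  class(e) <- "adnode"
  e
}

# Build an output node (or return plain numeric when nothing is tracked).
# `backward` is function(g) returning a list of gradients aligned to
# `inputs`; entries for non-node inputs are ignored.
ad_make <- function(value, inputs, backward) {
  if (!any(vapply(inputs, is_adnode, logical(1)))) return(value)
  e <- new.env(parent = emptyenv())
  e$value <- value
  e$grad <- NULL
  e$inputs <- inputs
  e$backward <- backward
  class(e) <- "adnode"
  e
}

acc_grad <- function(node, g) {
  node$grad <- if (is.null(node$grad)) g else node$grad + g
}

#' Run the backward pass from a scalar node
#'
#' Accumulates gradients into every upstream `adnode` (parameters included).
#' Parameter gradients persist until cleared with [ad_clear_grads()].
#' @param root scalar `adnode` (typically a loss).
#' @export
ad_backward <- function(root) {
  stopifnot(is_adnode(root), length(root$value) == 1L)
  # iterative post-order DFS over tracked inputs
  post <- vector("list", 256L); n_post <- 0L
  stack <- vector("list", 64L); n_st <- 1L
  stack[[1L]] <- root
  while (n_st > 0L) {
    node <- stack[[n_st]]
    st <- node$.state
    if (is.null(st)) {
      node$.state <- 1L
      kids <- node$inputs
      if (!is.null(kids)) {
        for (k in kids) {
          if (is_adnode(k) && is.null(k$.state)) {
            n_st <- n_st + 1L
            stack[[n_st]] <- k
          }
        }
      }
      if (identical(stack[[n_st]], node)) {
        # no unvisited children were pushed
        node$.state <- 2L
        n_post <- n_post + 1L
        post[[n_post]] <- node
        n_st <- n_st - 1L
      }
    } else if (st == 1L) {
      node$.state <- 2L
      n_post <- n_post + 1L
      post[[n_post]] <- node
      n_st <- n_st - 1L
    } else {
      n_st <- n_st - 1L # already emitted via another path
    }
  }
  root$grad <- 1
  for (i in seq.int(n_post, 1L)) {
    node <- post[[i]]
    node$.state <- NULL
    if (is.null(node$backward)) next
    if (is.null(node$grad)) next
    gs <- node$backward(node$grad)
    ins <- node$inputs
    for (j in seq_along(ins)) {
      if (is_adnode(ins[[j]]) && !is.null(gs[[j]])) acc_grad(ins[[j]], gs[[j]])
    }
    node$grad <- NULL # free intermediate gradients
  }
  invisible(root)
}

#' Clear accumulated gradients on a list of parameter nodes
#' @param params list of `adnode` parameters.
#' @export
ad_clear_grads <- function(params) {
  for (p in params) p$grad <- NULL
  invisible(params)
}

zeros_like <- function(v) {
  z <- v
  z[] <- 0
  z
}

# ---- elementwise arithmetic ------------------------------------------------

# reduce gradient g to the shape of target value tv (handles scalar operands)
shrink_to <- function(g, tv) if (length(tv) == 1L && length(g) > 1L) sum(g) else g

t_add <- function(a, b) {
  av <- ad_value(a); bv <- ad_value(b)
  ad_make(av + bv, list(a, b),
          function(g) list(shrink_to(g, av), shrink_to(g, bv)))
}

t_sub <- function(a, b) {
  av <- ad_value(a); bv <- ad_value(b)
  ad_make(av - bv, list(a, b),
          function(g) list(shrink_to(g, av), shrink_to(-g, bv)))
}

t_mul <- function(a, b) {
  av <- ad_value(a); bv <- ad_value(b)
  ad_make(av * bv, list(a, b),
          function(g) list(shrink_to(g * bv, av), shrink_to(g * av, bv)))
}

t_div <- function(a, b) {
  av <- ad_value(a); bv <- ad_value(b)
  ad_make(av / bv, list(a, b),
          function(g) list(shrink_to(g / bv, av),
                           shrink_to(-g * av / (bv * bv), bv)))
}

t_neg <- function(a) {
  av <- ad_value(a)
  ad_make(-av, list(a), function(g) list(-g))
}

# ---- linear algebra --------------------------------------------------------

t_matvec <- function(W, x) {
  Wv <- ad_value(W); xv <- ad_value(x)
  ad_make(as.numeric(Wv %*% xv), list(W, x),
          function(g) list(outer(as.numeric(g), as.numeric(xv)),
                           as.numeric(crossprod(Wv, g))))
}

t_dot <- function(a, b) {
  av <- ad_value(a); bv <- ad_value(b)
  ad_make(sum(av * bv), list(a, b),
          function(g) list(g * bv, g * av))
}

t_sum <- function(a) {
  av <- ad_value(a)
  ad_make(sum(av), list(a), function(g) {
    gr <- av; gr[] <- g; list(gr)
  })
}

t_mean <- function(a) {
  av <- ad_value(a); n <- length(av)
  ad_make(sum(av) / n, list(a), function(g) {
    gr <- av; gr[] <- g / n; list(gr)
  })
}

t_norm2sq <- function(a) {
  av <- ad_value(a)
  ad_make(sum(av * av), list(a), function(g) list(2 * g * av))
}

# ---- nonlinearities --------------------------------------------------------

t_tanh <- function(a) {
  y <- tanh(ad_value(a))
  ad_make(y, list(a), function(g) list(g * (1 - y * y)))
}

t_sigmoid <- function(a) {
  y <- 1 / (1 + exp(-ad_value(a)))
  ad_make(y, list(a), function(g) list(g * y * (1 - y)))
}

t_exp <- function(a) {
  y <- exp(ad_value(a))
  ad_make(y, list(a), function(g) list(g * y))
}

t_log <- function(a) {
  av <- ad_value(a)
  ad_make(log(av), list(a), function(g) list(g / av))
}

t_sqrt <- function(a) {
  y <- sqrt(ad_value(a))
  ad_make(y, list(a), function(g) list(g / (2 * y)))
}

t_square <- function(a) {
  av <- ad_value(a)
  ad_make(av * av, list(a), function(g) list(2 * g * av))
}

t_abs <- function(a) {
  av <- ad_value(a)
  ad_make(abs(av), list(a), function(g) list(g * sign(av)))
}

t_gelu <- function(a) {
  av <- ad_value(a)
  ad_make(av * pnorm(av), list(a),
          function(g) list(g * (pnorm(av) + av * dnorm(av))))
}

t_relu <- function(a) {
  av <- ad_value(a)
  ad_make(pmax(av, 0), list(a), function(g) list(g * (av > 0)))
}

t_leaky_relu <- function(a, slope = 0.2) {
  av <- ad_value(a)
  ad_make(ifelse(av > 0, av, slope * av), list(a),
          function(g) list(g * ifelse(av > 0, 1, slope)))
}

t_softmax <- function(a) {
  av <- ad_value(a)
  e <- exp(av - max(av))
  y <- e / sum(e)
  ad_make(y, list(a), function(g) list(y * (g - sum(g * y))))
}

# ---- shape manipulation ----------------------------------------------------

t_concat <- function(lst) {
  vals <- lapply(lst, ad_value)
  lens <- vapply(vals, length, integer(1))
  ad_make(unlist(vals, use.names = FALSE), lst, function(g) {
    off <- cumsum(c(0L, lens))
    lapply(seq_along(lst), function(i) {
      gi <- g[(off[i] + 1L):off[i + 1L]]
      tv <- vals[[i]]
      if (!is.null(dim(tv))) dim(gi) <- dim(tv)
      gi
    })
  })
}

t_index <- function(a, idx) {
  av <- ad_value(a)
  ad_make(av[idx], list(a), function(g) {
    gr <- zeros_like(av)
    gr[idx] <- g
    list(gr)
  })
}

t_cosine <- function(a, b) {
  t_div(t_dot(a, b), t_mul(t_sqrt(t_norm2sq(a)), t_sqrt(t_norm2sq(b))))
}

# ---- volumetric operators --------------------------------------------------

# 3D convolution on (H, W, D, Cin) with kernel (k, k, k, Cin, Cout)
t_conv3d <- function(x, w, stride = 1L, pad = 1L) {
  xv <- ad_value(x); wv <- ad_value(w)
  y <- conv3d_forward_cpp(xv, wv, as.integer(stride), as.integer(pad))
  ad_make(y, list(x, w), function(g) {
    if (is.null(dim(g))) dim(g) <- dim(y)
    bw <- conv3d_backward_cpp(xv, wv, g, as.integer(stride), as.integer(pad))
    list(bw$dx, bw$dw)
  })
}

# add per-channel bias b (length C) to (H, W, D, C)
t_bias4 <- function(x, b) {
  xv <- ad_value(x); bv <- ad_value(b)
  d <- dim(xv); nsp <- prod(d[1:3])
  ad_make(xv + rep(bv, each = nsp), list(x, b), function(g) {
    list(g, colSums(matrix(g, nrow = nsp)))
  })
}

# global average pooling: (H, W, D, C) -> length-C channel means
t_gap <- function(x) {
  xv <- ad_value(x)
  d <- dim(xv); nsp <- prod(d[1:3])
  ad_make(colMeans(matrix(xv, nrow = nsp)), list(x), function(g) {
    gr <- array(rep(g, each = nsp) / nsp, dim = d)
    list(gr)
  })
}

# region pooling: per-channel mean of (H, W, D, C) over the support of a
# binary 3D mask, so small regions are not diluted by the empty background
t_gap_masked <- function(x, mask) {
  xv <- ad_value(x)
  d <- dim(xv); nsp <- prod(d[1:3])
  mv <- as.numeric(mask)
  ns <- sum(mv)
  stopifnot(length(mv) == nsp, ns > 0)
  ad_make(colSums(matrix(xv, nrow = nsp) * mv) / ns, list(x), function(g) {
    gr <- array(rep(g, each = nsp) * mv / ns, dim = d)
    list(gr)
  })
}

# channel mean: (H, W, D, C) -> (H, W, D)
t_chanmean <- function(x) {
  xv <- ad_value(x)
  d <- dim(xv); nsp <- prod(d[1:3]); C <- d[4]
  y <- array(rowMeans(matrix(xv, nrow = nsp)), dim = d[1:3])
  ad_make(y, list(x), function(g) {
    gr <- array(rep(as.numeric(g), times = C) / C, dim = d)
    list(gr)
  })
}

# nearest-neighbour spatial upsampling by 2 on (H, W, D, C)
t_upsample2 <- function(x) {
  xv <- ad_value(x)
  d <- dim(xv)
  ih <- rep(seq_len(d[1]), each = 2L)
  iw <- rep(seq_len(d[2]), each = 2L)
  id <- rep(seq_len(d[3]), each = 2L)
  y <- xv[ih, iw, id, , drop = FALSE]
  ad_make(y, list(x), function(g) {
    if (is.null(dim(g))) dim(g) <- dim(y)
    g <- g[seq(1, 2 * d[1], 2), , , , drop = FALSE] +
      g[seq(2, 2 * d[1], 2), , , , drop = FALSE]
    g <- g[, seq(1, 2 * d[2], 2), , , drop = FALSE] +
      g[, seq(2, 2 * d[2], 2), , , drop = FALSE]
    g <- g[, , seq(1, 2 * d[3], 2), , drop = FALSE] +
      g[, , seq(2, 2 * d[3], 2), , drop = FALSE]
    list(g)
  })
}
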