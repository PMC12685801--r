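# Lobe adjacency, graph-attention normalization, message passing against a
# brute-force oracle, smoothness, concatenation, and the potential matrix.

test_that("adjacency schemes produce the expected edge sets", {
  lob <- build_adjacency(5, "lobar")
  expect_equal(nrow(lob$edges), 5L)
  expect_true(all(lob$edges[, 1] < lob$edges[, 2]))
  expect_equal(nrow(build_adjacency(3, "full")$edges), 3L)
  expect_equal(nrow(build_adjacency(6, "full")$edges), 15L)
  # custom matrix must be symmetric; edge lists need both directions
  A <- matrix(0, 3, 3); A[1, 2] <- 1
  expect_error(build_adjacency(3, "custom", A), "symmetric")
  expect_error(build_adjacency(3, "custom", rbind(c(1, 2))), "asymmetric")
  ok <- build_adjacency(3, "custom", rbind(c(1, 2), c(2, 1)))
  expect_equal(ok$edges, rbind(c(1L, 2L)))
  expect_error(build_adjacency(3, "custom", rbind(c(1, 4), c(4, 1))), "outside")
})

test_that("edge attention is a softmax over each neighbourhood", {
  set.seed(5)
  C <- 4
  par <- init_graph_params(C, d = 3, heads = 1L, seed = 2L)
  hs <- lapply(1:4, function(i) rnorm(C))
  # star graph: node 1 linked to 2, 3, 4
  adj <- build_adjacency(4, "custom",
                         rbind(c(1, 2), c(2, 1), c(1, 3), c(3, 1), c(1, 4), c(4, 1)))
  eta <- edge_attention(hs, adj, par)
  expect_equal(colSums(eta), rep(1, 4), tolerance = 1e-6)
  # hand-rolled oracle for the centre node
  logits <- vapply(2:4, function(j) {
    v <- c(par$h1_Wq %*% hs[[j]], par$h1_Wk %*% hs[[1]])
    sum(par$h1_a * ifelse(v > 0, v, 0.2 * v))
  }, numeric(1))
  expect_close(eta[2:4, 1], exp(logits) / sum(exp(logits)), 1e-6)
  # single neighbour -> weight 1; identical features -> equal split
  expect_equal(eta[1, 2], 1)
  hs2 <- list(hs[[1]], hs[[1]], hs[[1]], hs[[1]])
  eta2 <- edge_attention(hs2, adj, par)
  expect_equal(eta2[2:4, 1], rep(1 / 3, 3), tolerance = 1e-12)
})

test_that("message passing matches a per-node loop oracle", {
  set.seed(6)
  C <- 4; d <- 3
  par <- init_graph_params(C, d = d, heads = 2L, seed = 7L)
  hs <- lapply(1:3, function(i) rnorm(C))
  adj <- build_adjacency(3, "custom", rbind(c(1, 2), c(2, 1), c(2, 3), c(3, 2)))
  out <- message_pass(hs, adj, par)
  gelu <- function(x) x * pnorm(x)
  lrelu <- function(x) ifelse(x > 0, x, 0.2 * x)
  oracle <- lapply(1:3, function(k) {
    nb <- lobenet:::adj_neighbors(adj, k)
    msgs <- lapply(1:2, function(hd) {
      Wq <- par[[sprintf("h%d_Wq", hd)]]; Wk <- par[[sprintf("h%d_Wk", hd)]]
      a <- par[[sprintf("h%d_a", hd)]]; Wm <- par[[sprintf("h%d_Wmsg", hd)]]
      lg <- vapply(nb, function(j)
        sum(a * lrelu(c(Wq %*% hs[[j]], Wk %*% hs[[k]]))), numeric(1))
      eta <- exp(lg - max(lg)); eta <- eta / sum(eta)
      Reduce(`+`, lapply(seq_along(nb), function(m) eta[m] * as.numeric(Wm %*% hs[[nb[m]]])))
    })
    msg <- (msgs[[1]] + msgs[[2]]) / 2
    gelu(as.numeric(par$rho_W %*% msg) + par$rho_b) + as.numeric(par$Wres %*% hs[[k]])
  })
  for (k in 1:3) expect_close(out[[k]], oracle[[k]], 1e-6)
})

test_that("zero messages leave only the residual projection; symmetry holds", {
  C <- 4
  par <- init_graph_params(C, d = C, heads = 1L, seed = 3L)
  par$h1_Wmsg <- matrix(0, C, C)
  par$rho_b <- numeric(C)
  hs <- lapply(1:3, function(i) rnorm(C))
  adj <- build_adjacency(3, "full")
  out <- message_pass(hs, adj, par)
  for (k in 1:3)
    expect_close(out[[k]], as.numeric(par$Wres %*% hs[[k]]), 1e-12)
  # identical node features with shared parameters refine identically
  par2 <- init_graph_params(C, d = C, heads = 2L, seed = 4L)
  hs2 <- rep(list(rnorm(C)), 3)
  out2 <- message_pass(hs2, adj, par2)
  expect_close(out2[[1]], out2[[2]], 1e-12)
  expect_close(out2[[2]], out2[[3]], 1e-12)
})

test_that("isolated nodes fall back to a self-loop", {
  par <- init_graph_params(2, d = 2, heads = 1L, seed = 5L)
  adj <- build_adjacency(2, "custom", matrix(0, 2, 2))
  expect_equal(nrow(adj$edges), 0L)
  hs <- list(c(1, 2), c(3, 4))
  out <- message_pass(hs, adj, par)
  expect_length(out, 2L)
  expect_true(all(is.finite(unlist(out))))
})

test_that("graph smoothness is the per-edge squared distance sum", {
  hs <- list(c(1, 0), c(0, 0))
  e <- matrix(c(1, 2), 1)
  expect_equal(graph_smoothness(hs, e), 1)
  hs3 <- rep(list(c(2, 2, 2)), 4)
  expect_equal(graph_smoothness(hs3, build_adjacency(4, "full")), 0)
  expect_warning(val <- graph_smoothness(hs, matrix(integer(0), ncol = 2)), "empty")
  expect_equal(val, 0)
  # invariant to node relabeling; nonnegative
  set.seed(8)
  hr <- lapply(1:4, function(i) rnorm(3))
  adj <- build_adjacency(4, "full")
  perm <- c(4, 2, 1, 3)
  expect_equal(graph_smoothness(hr, adj), graph_smoothness(hr[perm], adj))
  expect_gte(graph_smoothness(hr, adj), 0)
})

test_that("concat descriptor is ordered, sized K*d, and splits back", {
  hs <- list(c(1, 2), c(3, 4), c(5, 6))
  g <- concat_descriptor(hs)
  expect_length(g, 6L)
  expect_equal(g, c(1, 2, 3, 4, 5, 6))
  expect_equal(concat_descriptor(rep(list(numeric(2)), 3)), numeric(6))
  back <- split(g, rep(1:3, each = 2))
  for (k in 1:3) expect_equal(unname(back[[k]]), hs[[k]])
})

test_that("potential matrix matches the double-loop cosine oracle", {
  set.seed(10)
  embs <- lapply(1:3, function(i) rmat(2, 4)) # 3 samples x 2 regions
  theta <- potential_matrix(embs)
  cosv <- function(a, b) sum(a * b) / sqrt(sum(a^2) * sum(b^2))
  oracle <- matrix(0, 2, 2)
  for (i in 1:2) for (j in 1:2)
    oracle[i, j] <- mean(vapply(embs, function(e) cosv(e[i, ], e[j, ]), numeric(1)))
  diag(oracle) <- 1
  expect_close(theta, oracle, 1e-10)
  expect_equal(theta, t(theta))
  # identical embeddings -> all ones; orthogonal -> zero off-diagonal
  same <- lapply(1:3, function(i) rbind(c(1, 1), c(1, 1)))
  expect_equal(potential_matrix(same), matrix(1, 2, 2))
  orth <- lapply(1:3, function(i) rbind(c(1, 0), c(0, 1)))
  expect_equal(potential_matrix(orth), diag(2))
  expect_warning(potential_matrix(list(rbind(c(0, 0), c(1, 2)))), "zero-norm")
})
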