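# Hierarchical attention and hypergraph convolution against loop oracles.

test_that("scaled_dot_score divides the dot product by the dimension", {
  expect_equal(scaled_dot_score(rep(0, 3), rep(0, 3)), 0)
  expect_equal(scaled_dot_score(rep(1, 4), rep(1, 4)), 1)
  q <- c(1, 2, -1); k <- c(0.5, 1, 3)
  expect_equal(scaled_dot_score(2 * q, k), 2 * scaled_dot_score(q, k))
  expect_equal(scaled_dot_score(q, k), sum(q * k) / 3)
})

test_that("hyperedge attention produces probability weights and matches the oracle", {
  set.seed(20)
  hg <- rand_hypergraph(15, 9, 20)
  X <- matrix(rnorm(15 * 6), 15, 6)
  p <- withr::with_seed(1, init_encoder_params(6, 4))
  E <- hyperedge_attention(hg, X, p)
  expect_equal(E, loop_hyperedge_attention(hg$H, X, p$W1, p$u),
               tolerance = 1e-10)

  # singleton hyperedge: weight 1, representation = projected member
  H1 <- cbind(c(1, 0, 0), c(1, 1, 1))
  hg1 <- hypermda:::new_hypergraph(H1, "View1")
  X1 <- matrix(rnorm(9), 3, 3)
  p1 <- withr::with_seed(2, init_encoder_params(3, 4))
  E1 <- hyperedge_attention(hg1, X1, p1)
  expect_equal(E1[1, ], as.vector(X1[1, , drop = FALSE] %*% p1$W1))

  # identical member features share the weight equally
  X2 <- X1; X2[2, ] <- X2[3, ]
  H2 <- matrix(c(0, 1, 1), 3, 1)
  hg2 <- hypermda:::new_hypergraph(cbind(diag(3), H2), "View1")
  E2 <- hyperedge_attention(hg2, X2, p1)
  expect_equal(E2[4, ], as.vector(X2[2, , drop = FALSE] %*% p1$W1))
})

test_that("node attention yields probability weights and matches the oracle", {
  set.seed(21)
  hg <- rand_hypergraph(15, 9, 21)
  X <- matrix(rnorm(15 * 6), 15, 6)
  p <- withr::with_seed(3, init_encoder_params(6, 4))
  E <- hyperedge_attention(hg, X, p)
  Z <- node_attention(hg, E, X, p)
  expect_equal(Z, loop_node_attention(hg$H, E, X, p$W2, p$W3, p$phi),
               tolerance = 1e-10)
})

test_that("attention weights are probability vectors at both levels", {
  set.seed(22)
  hg <- rand_hypergraph(12, 7, 22)
  X <- matrix(rnorm(12 * 5), 12, 5)
  p <- withr::with_seed(4, init_encoder_params(5, 6))
  for (norm in c("softmax")) {
    d <- ncol(p$W1)
    Xp <- X %*% p$W1
    s <- (Xp %*% p$u) / d
    a <- hypermda:::ad_masked_softmax_cols(s %*% matrix(1, 1, 7), hg$H)
    expect_true(all(a >= 0))
    expect_equal(unname(colSums(a)), rep(1, 7), tolerance = 1e-8)
  }
})

test_that("hgcn_forward reproduces the dense propagation oracle", {
  set.seed(23)
  hg <- rand_hypergraph(12, 6, 23)
  Z0 <- matrix(rnorm(12 * 4), 12, 4)
  theta <- diag(4)
  p <- list(theta = list(theta))
  # one layer, identity weights, identity activation (final layer)
  got <- hgcn_forward(hg, Z0, p, L = 1)
  expect_equal(got, loop_hgcn_layer(hg$H, hg$W, Z0, theta), tolerance = 1e-10)

  # zero input stays zero through bias-free layers
  p2 <- withr::with_seed(5, init_encoder_params(4, 4))
  expect_equal(hgcn_forward(hg, Z0 * 0, p2), matrix(0, 12, 4))

  # two nodes sharing one hyperedge with equal rows keep equal rows
  hg2 <- hypermda:::new_hypergraph(matrix(1, 2, 1), "View1")
  Z2 <- matrix(1, 2, 3)
  got2 <- hgcn_forward(hg2, Z2, list(theta = list(diag(3))), L = 1)
  expect_equal(got2[1, ], got2[2, ])
})

test_that("the full encoder is node-permutation equivariant and matches loops", {
  set.seed(24)
  n <- 14
  hg <- rand_hypergraph(n, 8, 24)
  X <- matrix(rnorm(n * 5), n, 5)
  p <- withr::with_seed(6, init_encoder_params(5, 4))
  Z <- encode_view(hg, X, p)

  # independent loop reference: attention stages + explicit propagation
  E_o <- loop_hyperedge_attention(hg$H, X, p$W1, p$u)
  Z0_o <- loop_node_attention(hg$H, E_o, X, p$W2, p$W3, p$phi)
  l1 <- loop_hgcn_layer(hg$H, hg$W, Z0_o, p$theta[[1]])
  l1 <- pmax(l1, 0)
  Z_o <- loop_hgcn_layer(hg$H, hg$W, l1, p$theta[[2]])
  expect_equal(Z, Z_o, tolerance = 1e-6)

  # permuting nodes (rows of X and of H) permutes the embeddings
  perm <- sample(n)
  hgp <- hypermda:::new_hypergraph(hg$H[perm, ], "View1")
  Zp <- encode_view(hgp, X[perm, ], p)
  expect_equal(Zp, Z[perm, ], tolerance = 1e-10)

  # NoDHA path: direct projection into the convolution stack
  Zn <- encode_view(hg, X, p, use_dha = FALSE)
  l1n <- pmax(loop_hgcn_layer(hg$H, hg$W, X %*% p$W1, p$theta[[1]]), 0)
  expect_equal(Zn, loop_hgcn_layer(hg$H, hg$W, l1n, p$theta[[2]]),
               tolerance = 1e-6)
})

test_that("ratio normalization implements the literal ratio form", {
  # positive scores: ratio weights are score / sum(score) within the mask
  H <- cbind(c(1, 1, 0), c(0, 1, 1))
  s <- matrix(c(1, 2, 3), 3, 2)
  got <- hypermda:::ad_masked_ratio_cols(s, H)
  expect_equal(got[, 1], c(1 / 3, 2 / 3, 0))
  expect_equal(got[, 2], c(0, 2 / 5, 3 / 5))
})
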