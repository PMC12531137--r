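# Gating, inter-view attention, decoding and losses.

test_that("view_gate matches a loop oracle and keeps gates in (0,1)", {
  set.seed(40)
  d <- 6
  ip <- withr::with_seed(8, init_integration_params(d))
  Z <- matrix(rnorm(10 * d), 10, d)
  got <- view_gate(Z, ip$gate_v1)

  pooled <- colMeans(Z)
  h <- pmax(as.vector(pooled %*% ip$gate_v1$W1) + as.vector(ip$gate_v1$b1), 0)
  g <- 1 / (1 + exp(-(as.vector(h %*% ip$gate_v1$W2) + as.vector(ip$gate_v1$b2))))
  expect_true(all(g > 0 & g < 1))
  oracle <- matrix(0, 10, d)
  for (i in 1:10) for (j in 1:d) oracle[i, j] <- max(g[j] * Z[i, j], 0)
  expect_equal(got, oracle, tolerance = 1e-10)

  expect_equal(view_gate(Z * 0, ip$gate_v1), matrix(0, 10, d))
})

test_that("inter-view attention is a convex combination matching the loop oracle", {
  set.seed(41)
  d <- 4; n <- 6
  ip <- withr::with_seed(9, init_integration_params(d))
  Z1 <- matrix(rnorm(n * d), n, d)
  Z2 <- matrix(rnorm(n * d), n, d)
  got <- interview_attention(Z1, Z2, ip, n_heads = 1)

  # single-head per-node oracle
  oracle <- matrix(0, n, d)
  for (i in seq_len(n)) {
    P <- rbind(Z1[i, ], Z2[i, ])
    Q <- P %*% ip$Wq; K <- P %*% ip$Wk; V <- P %*% ip$Wv
    S <- (Q %*% t(K)) / d
    A <- t(apply(S, 1, function(r) exp(r - max(r)) / sum(exp(r - max(r)))))
    expect_equal(rowSums(A), c(1, 1), tolerance = 1e-8)
    att <- A %*% V
    oracle[i, ] <- as.vector(c(att[1, ], att[2, ]) %*% ip$Wh) + as.vector(ip$bh)
  }
  expect_equal(got, oracle, tolerance = 1e-8)

  # identical views attend 0.5/0.5 and multi-head averaging is exact
  got_same <- interview_attention(Z1, Z1, ip, n_heads = 2)
  half <- matrix(0, n, d)
  for (i in seq_len(n)) {
    P <- rbind(Z1[i, ], Z1[i, ])
    V <- P %*% ip$Wv
    att <- rbind(0.5 * V[1, ] + 0.5 * V[2, ], 0.5 * V[1, ] + 0.5 * V[2, ])
    half[i, ] <- as.vector(c(att[1, ], att[2, ]) %*% ip$Wh) + as.vector(ip$bh)
  }
  expect_equal(got_same, half, tolerance = 1e-8)
})

test_that("decode_scores is the inner product of decoded embeddings", {
  d <- 4
  idp <- list(Wdec = diag(d), bdec = matrix(0, 1, d))
  Hm <- diag(d)[1:3, , drop = FALSE]
  Hd <- diag(d)[1:4, , drop = FALSE]
  As <- decode_scores(Hm, Hd, idp, idp)
  expect_equal(As, diag(1, 3, 4))

  set.seed(42)
  pm <- withr::with_seed(10, init_integration_params(d))
  pd <- withr::with_seed(11, init_integration_params(d))
  Hm <- matrix(rnorm(12), 3, d); Hd <- matrix(rnorm(20), 5, d)
  As2 <- decode_scores(Hm, Hd, pm, pd)
  expect_equal(dim(As2), c(3, 5))
  Ym <- Hm %*% pm$Wdec + rep(1, 3) %o% as.vector(pm$bdec)
  Yd <- Hd %*% pd$Wdec + rep(1, 5) %o% as.vector(pd$bdec)
  oracle <- matrix(0, 3, 5)
  for (i in 1:3) for (j in 1:5) oracle[i, j] <- sum(Ym[i, ] * Yd[j, ])
  expect_equal(As2, oracle, tolerance = 1e-10)
  # inner-product decoder has rank at most d
  expect_lte(qr(decode_scores(matrix(rnorm(40), 10, d),
                              matrix(rnorm(48), 12, d), pm, pd))$rank, d)
})

test_that("reconstruction loss reproduces the worked example and decomposes", {
  A <- matrix(c(1, 0), 1, 2)
  As <- matrix(0, 1, 2)
  obs <- matrix(c(1, 0), 1, 2)
  unobs <- matrix(c(0, 1), 1, 2)
  expect_equal(as.numeric(reconstruction_loss(A, As, obs, unobs, 0.11)),
               0.445)
  # perfect reconstruction gives zero
  expect_equal(as.numeric(reconstruction_loss(A, A, obs, unobs, 0.11)), 0)
  # alpha = 1 removes the observed term entirely
  expect_equal(as.numeric(reconstruction_loss(A, As, obs, unobs, 1)), 0)
  # only the unobserved cell contributes: 1/2 * (0 - 5)^2
  expect_equal(as.numeric(reconstruction_loss(A, As + 5, obs, unobs, 1)), 12.5)

  set.seed(43)
  A2 <- matrix(rbinom(30, 1, 0.3), 5, 6)
  As2 <- matrix(rnorm(30), 5, 6)
  obs2 <- (A2 == 1) * 1
  unobs2 <- (A2 == 0) * 1
  expect_equal(as.numeric(reconstruction_loss(A2, As2, obs2, unobs2, 0.11)),
               loop_reconstruction(A2, As2, obs2, unobs2, 0.11),
               tolerance = 1e-10)
  # decomposability: full loss = observed-only + unobserved-only pieces
  zero <- matrix(0, 5, 6)
  expect_equal(as.numeric(reconstruction_loss(A2, As2, obs2, unobs2, 0.11)),
               as.numeric(reconstruction_loss(A2, As2, obs2, zero, 0.11)) +
               as.numeric(reconstruction_loss(A2, As2, zero, unobs2, 0.11)))
  expect_error(reconstruction_loss(A2, As2, obs2, obs2, 0.11), "overlap")
})

test_that("total loss combines components linearly", {
  expect_equal(as.numeric(total_loss(1, 2, 3)), 6)
  expect_equal(as.numeric(total_loss(1, 2, 3, 0, 0)), 1)
  expect_equal(as.numeric(total_loss(2, 3, 5, 0.5, 2)), 2 + 1.5 + 10)
})
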