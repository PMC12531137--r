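# Independent pure-loop reference implementations used as oracles. These
# deliberately avoid the package's vectorized code paths: everything is
# written as explicit per-element loops over the defining formulas.

# random symmetric similarity matrix with unit diagonal
rand_sim <- function(n, seed) {
  set.seed(seed)
  S <- matrix(runif(n * n), n)
  S <- (S + t(S)) / 2
  diag(S) <- 1
  S
}

# small random hypergraph: every node in its own hyperedge plus random
# extra memberships, so no empty hyperedge and no isolated node
rand_hypergraph <- function(n, e, seed) {
  set.seed(seed)
  H <- matrix(rbinom(n * e, 1, 0.3), n, e)
  for (j in seq_len(e)) if (sum(H[, j]) == 0) H[sample(n, 1), j] <- 1
  for (i in seq_len(n)) if (sum(H[i, ]) == 0) H[i, sample(e, 1)] <- 1
  hypermda:::new_hypergraph(H, "View1")
}

# Eq.-style local KNN kernel by explicit loops
loop_local_kernel <- function(S, k) {
  n <- nrow(S)
  K <- matrix(0, n, n)
  for (i in seq_len(n)) {
    s <- S[i, ]
    s[i] <- -Inf
    nb <- order(-s, seq_len(n))[seq_len(k)]
    tot <- sum(S[i, nb])
    if (tot > 0) for (j in nb) K[i, j] <- S[i, j] / tot
  }
  K
}

softmax <- function(x) { e <- exp(x - max(x)); e / sum(e) }

# hyperedge-level attention by loops: scores s_i = (W1' n_i)' u / d,
# softmax within each hyperedge, e_j = sum a_ji (W1' n_i)
loop_hyperedge_attention <- function(H, X, W1, u) {
  d <- ncol(W1)
  Xp <- X %*% W1
  s <- as.vector(Xp %*% u) / d
  E <- matrix(0, ncol(H), d)
  for (j in seq_len(ncol(H))) {
    members <- which(H[, j] == 1)
    a <- softmax(s[members])
    for (m in seq_along(members)) {
      E[j, ] <- E[j, ] + a[m] * Xp[members[m], ]
    }
  }
  E
}

# node-level attention by loops: scores (W2' e_j)' (W3' n_i) / d, softmax
# over incident hyperedges, node update phi(sum b_ij W2' e_j)
loop_node_attention <- function(H, E, X, W2, W3, phi) {
  d <- ncol(W2)
  Ni <- X %*% W3
  Ej <- E %*% W2
  Z <- matrix(0, nrow(H), d)
  for (i in seq_len(nrow(H))) {
    inc <- which(H[i, ] == 1)
    sc <- vapply(inc, function(j) sum(Ni[i, ] * Ej[j, ]) / d, numeric(1))
    b <- softmax(sc)
    acc <- numeric(d)
    for (m in seq_along(inc)) acc <- acc + b[m] * Ej[inc[m], ]
    h <- as.vector(acc %*% phi$W1) + as.vector(phi$b1)
    h <- ifelse(h > 0, h, exp(h) - 1)
    Z[i, ] <- as.vector(h %*% phi$W2) + as.vector(phi$b2)
  }
  Z
}

# one HGCN layer by explicit degree-normalized propagation
loop_hgcn_layer <- function(H, w, Z, theta) {
  n <- nrow(H)
  dv <- as.vector(H %*% w)
  de <- colSums(H)
  P <- matrix(0, n, n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    acc <- 0
    for (e in seq_len(ncol(H))) {
      acc <- acc + H[i, e] * w[e] * H[j, e] / de[e]
    }
    P[i, j] <- acc / sqrt(dv[i]) / sqrt(dv[j])
  }
  P %*% Z %*% theta
}

# InfoNCE by triple loops on plain embeddings (identity projection head)
loop_info_nce <- function(V, U, tau) {
  n <- nrow(V)
  cosine <- function(a, b) sum(a * b) / ((sqrt(sum(a^2)) + 1e-12) * (sqrt(sum(b^2)) + 1e-12))
  total <- 0
  for (i in seq_len(n)) {
    pos <- exp(cosine(V[i, ], U[i, ]) / tau)
    den <- pos
    for (k in seq_len(n)) {
      if (k == i) next
      den <- den + exp(cosine(V[i, ], V[k, ]) / tau)
      den <- den + exp(cosine(V[i, ], U[k, ]) / tau)
    }
    total <- total - log(pos / den)
  }
  total
}

# weighted Frobenius reconstruction loss by loops
loop_reconstruction <- function(A, As, obs, unobs, alpha) {
  t1 <- 0; t2 <- 0
  for (i in seq_len(nrow(A))) for (j in seq_len(ncol(A))) {
    d2 <- (A[i, j] - As[i, j])^2
    if (obs[i, j] == 1) t1 <- t1 + d2
    if (unobs[i, j] == 1) t2 <- t2 + d2
  }
  (1 - alpha) / 2 * t1 + alpha / 2 * t2
}

# O(n^2) Wilcoxon-Mann-Whitney AUC by pair counting
loop_auc <- function(scores, labels) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  acc <- 0
  for (p in pos) for (q in neg) {
    acc <- acc + (p > q) + 0.5 * (p == q)
  }
  acc / (length(pos) * length(neg))
}

# small synthetic dataset + config used by several training tests
tiny_synth <- function(seed = 3) {
  generate_dataset(synthetic_spec(n_microbes = 15, n_drugs = 24,
                                  target_density = 0.15, seed = seed))
}

tiny_config <- function(epochs = 5, ...) {
  mda_config(embed_dim = 8, n_heads = 2, epochs = epochs, knn_k = 3, ko_c = 3,
             snf_k = 3, learning_rate = 1e-3, seed = 11, ...)
}
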