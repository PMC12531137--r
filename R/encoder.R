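# Hierarchical attention encoder: hyperedge-level attention over member
# nodes, node-level attention over incident hyperedges, then spectral
# hypergraph convolution. All functions accept plain matrices or autodiff
# tape nodes for the parameters; hypergraph and features are always plain.

#' Scaled dot-product score
#'
#' `S(q, k) = (q' k) / D` with `D` the common length of the two vectors.
#' Note the divisor is the dimension itself, not its square root.
#'
#' @param q,k numeric vectors of equal length.
#' @return A scalar score.
#' @export
scaled_dot_score <- function(q, k) {
  q <- as.vector(q); k <- as.vector(k)
  stopifnot(length(q) == length(k))
  sum(q * k) / length(q)
}

#' Initialize encoder parameters
#'
#' Glorot-uniform initialization of one hierarchical-attention + HGCN
#' encoder: node projection `W1` (F x d), context vector `u` (d x 1),
#' hyperedge projection `W2` (d x d), node score projection `W3` (F x d),
#' the two-layer ELU node-update MLP `phi`, and `L` convolution weight
#' matrices `theta`. Draws from the current RNG state.
#'
#' @param n_features input feature dimension F.
#' @param d embedding dimension.
#' @param n_layers number of convolution layers.
#' @return Named list of parameter matrices.
#' @export
init_encoder_params <- function(n_features, d, n_layers = 2L) {
  list(W1 = glorot(n_features, d),
       u = glorot(d, 1L),
       W2 = glorot(d, d),
       W3 = glorot(n_features, d),
       phi = list(W1 = glorot(d, d), b1 = matrix(0, 1L, d),
                  W2 = glorot(d, d), b2 = matrix(0, 1L, d)),
       theta = lapply(seq_len(n_layers), function(l) glorot(d, d)))
}

# Normalize raw scores into attention weights within each column's mask.
.attn_norm <- function(scores, mask, norm) {
  if (norm == "softmax") ad_masked_softmax_cols(scores, mask)
  else ad_masked_ratio_cols(scores, mask)
}

#' Hyperedge-level attention
#'
#' For each hyperedge j, attention weights over its member nodes are formed
#' from the scaled dot-product of each member's projected feature `W1 n_i`
#' against the trainable context vector `u`, normalized within the
#' hyperedge; the hyperedge representation is the weighted sum
#' `e_j = sum_i a_ji (W1 n_i)`.
#'
#' @param hg a `"hypergraph"`.
#' @param X feature matrix (N x F), rows = hypergraph nodes.
#' @param params encoder parameters ([init_encoder_params()]).
#' @param norm `"softmax"` (default) or `"ratio"` normalization of scores.
#' @return Hyperedge representation matrix (E x d).
#' @export
hyperedge_attention <- function(hg, X, params, norm = c("softmax", "ratio")) {
  norm <- match.arg(norm)
  stopifnot(inherits(hg, "hypergraph"))
  d <- ncol(ad_val(params$W1))
  Xp <- ad_matmul(X, params$W1)                       # N x d
  s <- ad_scale(ad_matmul(Xp, params$u), 1 / d)       # N x 1
  scores <- ad_matmul(s, matrix(1, 1L, ncol(hg$H)))   # N x E broadcast
  a <- .attn_norm(scores, hg$H, norm)                 # N x E, columns sum 1
  ad_matmul(ad_transpose(a), Xp)                      # E x d
}

#' Node-level attention and node update
#'
#' For each node i, attention weights over its incident hyperedges come from
#' the scaled dot-product of `W2 e_j` against `W3 n_i`, normalized over the
#' incident set; the node embedding is
#' `Z_i = phi(sum_j b_ij (W2 e_j))` with `phi` a two-layer MLP with an ELU
#' activation between the layers.
#'
#' @param hg a `"hypergraph"`.
#' @param E_rep hyperedge representations from [hyperedge_attention()].
#' @param X feature matrix (N x F).
#' @param params encoder parameters.
#' @param norm score normalization mode.
#' @return Node embedding matrix (N x d).
#' @export
node_attention <- function(hg, E_rep, X, params, norm = c("softmax", "ratio")) {
  norm <- match.arg(norm)
  stopifnot(inherits(hg, "hypergraph"))
  d <- ncol(ad_val(params$W2))
  Ni <- ad_matmul(X, params$W3)                       # N x d
  Ej <- ad_matmul(E_rep, params$W2)                   # E x d
  S <- ad_scale(ad_matmul(Ni, ad_transpose(Ej)), 1 / d)  # N x E
  bt <- .attn_norm(ad_transpose(S), t(hg$H), norm)    # E x N, masked per node
  b <- ad_transpose(bt)                               # N x E, rows sum 1
  Z0 <- ad_matmul(b, Ej)                              # sum_j b_ij (W2 e_j)
  h <- ad_elu(ad_add_bias(ad_matmul(Z0, params$phi$W1), params$phi$b1))
  ad_add_bias(ad_matmul(h, params$phi$W2), params$phi$b2)
}

# Dense symmetric-normalized propagation matrix
# Dv^{-1/2} H W De^{-1} H' Dv^{-1/2} of a hypergraph (a plain constant).
hgcn_propagation <- function(hg) {
  deg <- degree_matrices(hg)
  Hs <- hg$H * (1 / sqrt(deg$d_v))
  P <- Hs %*% (t(Hs) * (hg$W / deg$d_e))
  P
}

#' Hypergraph convolution forward pass
#'
#' Applies `L` spectral convolution layers
#' `X^{l+1} = sigma(Dv^{-1/2} H W De^{-1} H' Dv^{-1/2} X^l theta_l)` with
#' ReLU on hidden layers and identity on the final layer (embeddings stay
#' unrestricted in sign for the inner-product decoder).
#'
#' @param hg a `"hypergraph"` with strictly positive degrees.
#' @param Z0 input node embeddings (N x d).
#' @param params encoder parameters carrying `theta`, a list of `L` weight
#'   matrices.
#' @param L number of layers; defaults to `length(params$theta)`.
#' @return Node embeddings (N x d).
#' @export
hgcn_forward <- function(hg, Z0, params, L = length(params$theta)) {
  stopifnot(L >= 1, L <= length(params$theta))
  P <- hgcn_propagation(hg)
  Z <- Z0
  for (l in seq_len(L)) {
    Z <- ad_matmul(P, ad_matmul(Z, params$theta[[l]]))
    if (l < L) Z <- ad_relu(Z)
  }
  Z
}

#' Full encoder for one hypergraph view
#'
#' Hierarchical attention followed by hypergraph convolution. With
#' `use_dha = FALSE` the attention stage is replaced by a direct feature
#' projection `X W1` (the NoDHA ablation).
#'
#' @param hg a `"hypergraph"`.
#' @param X feature matrix.
#' @param params encoder parameters.
#' @param norm attention score normalization.
#' @param use_dha logical; apply the hierarchical attention stage.
#' @return Node embeddings (N x d).
#' @export
encode_view <- function(hg, X, params, norm = "softmax", use_dha = TRUE) {
  Z0 <- if (use_dha) {
    E_rep <- hyperedge_attention(hg, X, params, norm)
    node_attention(hg, E_rep, X, params, norm)
  } else {
    ad_matmul(X, params$W1)
  }
  hgcn_forward(hg, Z0, params)
}
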