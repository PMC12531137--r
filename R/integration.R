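# View gating, multi-head inter-view attention fusion, inner-product
# decoding and the training losses.

#' Initialize integration and decoder parameters for one entity type
#'
#' Per view, a squeeze-and-excitation style gate (global average pooling
#' over nodes followed by a two-layer FNN with ReLU then sigmoid); shared
#' Q/K/V projections and the feedforward `Wh` (2d -> d) of the inter-view
#' attention; and the final affine decoder map (d -> d).
#'
#' @param d embedding dimension.
#' @return Named list of parameter matrices.
#' @export
init_integration_params <- function(d) {
  gate <- function() list(W1 = glorot(d, d), b1 = matrix(0, 1L, d),
                          W2 = glorot(d, d), b2 = matrix(0, 1L, d))
  list(gate_v1 = gate(), gate_v2 = gate(),
       Wq = glorot(d, d), Wk = glorot(d, d), Wv = glorot(d, d),
       Wh = glorot(2L * d, d), bh = matrix(0, 1L, d),
       Wdec = glorot(d, d), bdec = matrix(0, 1L, d))
}

#' Gate a view's embeddings
#'
#' Column-wise mean over nodes produces a d-vector; a two-layer FNN (ReLU
#' then sigmoid) turns it into a per-feature gate in (0,1)^d which scales
#' every node's embedding, followed by a ReLU.
#'
#' @param Z node embeddings (N x d).
#' @param gate gate parameters (one of `gate_v1`/`gate_v2` from
#'   [init_integration_params()]).
#' @return Gated embeddings (N x d).
#' @export
view_gate <- function(Z, gate) {
  pooled <- ad_colmeans(Z)
  h <- ad_relu(ad_add_bias(ad_matmul(pooled, gate$W1), gate$b1))
  g <- ad_sigmoid(ad_add_bias(ad_matmul(h, gate$W2), gate$b2))
  ad_relu(ad_rowbroadcast_mul(g, Z))
}

#' Multi-head inter-view attention fusion
#'
#' For every node, its two view embeddings are stacked into a 2 x d pair and
#' projected to queries, keys and values. Each head scores the 2 x 2
#' inter-view attention from its own feature sub-block (scaled by the full
#' dimension d, as a deliberate fidelity choice over sqrt(d)), applies the
#' attention to the full value vectors, and the head outputs are averaged.
#' The fused node vector is the feedforward `Wh` applied to the
#' row-concatenation of the two attended view vectors.
#'
#' @param Z1,Z2 gated view embeddings (N x d).
#' @param params integration parameters ([init_integration_params()]).
#' @param n_heads number of attention heads; the feature axis is split
#'   into `n_heads` contiguous sub-blocks of near-equal size.
#' @return Fused embeddings (N x d).
#' @export
interview_attention <- function(Z1, Z2, params, n_heads = 1L) {
  d <- ncol(ad_val(Z1))
  stopifnot(n_heads >= 1, n_heads <= d)
  blocks <- split(seq_len(d), rep(seq_len(n_heads),
                                  diff(floor(seq(0, d, length.out = n_heads + 1)))))
  Q1 <- ad_matmul(Z1, params$Wq); Q2 <- ad_matmul(Z2, params$Wq)
  K1 <- ad_matmul(Z1, params$Wk); K2 <- ad_matmul(Z2, params$Wk)
  V1 <- ad_matmul(Z1, params$Wv); V2 <- ad_matmul(Z2, params$Wv)
  M11 <- ad_mul(Q1, K1); M12 <- ad_mul(Q1, K2)
  M21 <- ad_mul(Q2, K1); M22 <- ad_mul(Q2, K2)
  A1 <- NULL; A2 <- NULL
  for (h in seq_len(n_heads)) {
    cols <- blocks[[h]]
    s11 <- ad_scale(ad_rowsums_cols(M11, cols), 1 / d)
    s12 <- ad_scale(ad_rowsums_cols(M12, cols), 1 / d)
    s21 <- ad_scale(ad_rowsums_cols(M21, cols), 1 / d)
    s22 <- ad_scale(ad_rowsums_cols(M22, cols), 1 / d)
    a11 <- ad_sigmoid(ad_sub(s11, s12))  # softmax over the two views
    a12 <- ad_sigmoid(ad_sub(s12, s11))
    a21 <- ad_sigmoid(ad_sub(s21, s22))
    a22 <- ad_sigmoid(ad_sub(s22, s21))
    att1 <- ad_add(ad_colbroadcast_mul(a11, V1), ad_colbroadcast_mul(a12, V2))
    att2 <- ad_add(ad_colbroadcast_mul(a21, V1), ad_colbroadcast_mul(a22, V2))
    A1 <- if (is.null(A1)) att1 else ad_add(A1, att1)
    A2 <- if (is.null(A2)) att2 else ad_add(A2, att2)
  }
  A1 <- ad_scale(A1, 1 / n_heads)
  A2 <- ad_scale(A2, 1 / n_heads)
  ad_add_bias(ad_matmul(ad_hcat(A1, A2), params$Wh), params$bh)
}

#' Decode association scores
#'
#' Applies the per-entity affine decoder to the fused embeddings and forms
#' the score matrix by the inner product `As = Ym %*% t(Yd)`.
#'
#' @param Hm,Hd fused microbe / drug embeddings (Nm x d, Nd x d).
#' @param params_m,params_d integration parameter lists carrying `Wdec`,
#'   `bdec`.
#' @return Real-valued score matrix (Nm x Nd).
#' @export
decode_scores <- function(Hm, Hd, params_m, params_d) {
  Ym <- ad_add_bias(ad_matmul(Hm, params_m$Wdec), params_m$bdec)
  Yd <- ad_add_bias(ad_matmul(Hd, params_d$Wdec), params_d$bdec)
  ad_matmul(Ym, ad_transpose(Yd))
}

#' Weighted Frobenius reconstruction loss
#'
#' `(1 - alpha)/2 * ||P_obs(A - As)||_F^2 + alpha/2 * ||P_unobs(A - As)||_F^2`;
#' entries in neither mask contribute nothing (e.g. held-out test pairs).
#'
#' @param A binary association matrix.
#' @param As score matrix of the same shape.
#' @param observed_mask,unobserved_mask disjoint binary masks.
#' @param alpha trade-off in \[0, 1\].
#' @return Scalar loss.
#' @export
reconstruction_loss <- function(A, As, observed_mask, unobserved_mask, alpha) {
  stopifnot(alpha >= 0, alpha <= 1)
  if (any(observed_mask * unobserved_mask != 0)) {
    stop("observed and unobserved masks overlap")
  }
  Dif <- ad_sub(A, As)
  sq <- ad_mul(Dif, Dif)
  t_obs <- ad_sum(ad_mul(sq, observed_mask))
  t_un <- ad_sum(ad_mul(sq, unobserved_mask))
  ad_add(ad_scale(t_obs, (1 - alpha) / 2), ad_scale(t_un, alpha / 2))
}

#' Total training loss
#'
#' `L = L_RE + lambda_m * L_cl_m + gamma_d * L_cl_d`.
#'
#' @param L_RE reconstruction loss.
#' @param L_cl_m,L_cl_d contrastive losses.
#' @param lambda_m,gamma_d weights (both default 1).
#' @return Scalar loss.
#' @export
total_loss <- function(L_RE, L_cl_m, L_cl_d, lambda_m = 1, gamma_d = 1) {
  ad_add(L_RE, ad_add(ad_scale(L_cl_m, lambda_m), ad_scale(L_cl_d, gamma_d)))
}
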