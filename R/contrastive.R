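# Dual-view InfoNCE contrastive objective. The positive pair for node i is
# its embedding in the other hypergraph view; negatives are every other
# node's embedding in both views.

#' Initialize a projection head
#'
#' Two affine maps (d -> d -> d) with an ELU between them, applied to
#' embeddings before the contrastive similarity.
#'
#' @param d embedding dimension.
#' @return Named list of parameter matrices.
#' @export
init_projection_head <- function(d) {
  list(W1 = glorot(d, d), b1 = matrix(0, 1L, d),
       W2 = glorot(d, d), b2 = matrix(0, 1L, d))
}

project_head <- function(Z, head) {
  if (is.null(head)) return(Z)
  h <- ad_elu(ad_add_bias(ad_matmul(Z, head$W1), head$b1))
  ad_add_bias(ad_matmul(h, head$W2), head$b2)
}

# L2-normalize rows. The guard sits inside the sqrt (norm becomes
# sqrt(||x||^2 + 1e-24), i.e. ~1e-12 for a zero row) so that both the
# cosine and its gradient stay finite for exactly-zero embedding rows.
normalize_rows <- function(Z) {
  rs <- ad_rowsums(ad_mul(Z, Z))
  inv <- ad_div(1, ad_sqrt(ad_shift(rs, 1e-24)))
  ad_colbroadcast_mul(inv, Z)
}

#' InfoNCE contrastive loss between two views
#'
#' Anchored on view `V`: for each row i the positive is row i of `U`, and
#' the negatives are all other rows of `V` (intra-view) and of `U`
#' (cross-view). Similarity is the cosine of the projected embeddings,
#' scaled by the temperature `tau`. Returns the sum over anchors of
#' `-log( exp(s(i,i)/tau) / (exp(s(i,i)/tau) + sum_{k != i} exp(s_vv(i,k)/tau)
#'  + sum_{k != i} exp(s_vu(i,k)/tau)) )`.
#'
#' @param V,U embedding matrices (N x d), rows indexing the same entities.
#' @param head projection head ([init_projection_head()]) or `NULL` for the
#'   identity.
#' @param tau temperature, > 0.
#' @return Scalar loss (1 x 1 matrix when any input is a tape node).
#' @export
info_nce <- function(V, U, head = NULL, tau = 0.5) {
  stopifnot(tau > 0)
  n <- nrow(ad_val(V))
  Vn <- normalize_rows(project_head(V, head))
  Un <- normalize_rows(project_head(U, head))
  Svu <- ad_scale(ad_matmul(Vn, ad_transpose(Un)), 1 / tau)
  Svv <- ad_scale(ad_matmul(Vn, ad_transpose(Vn)), 1 / tau)
  offdiag <- 1 - diag(n)
  denom <- ad_add(ad_rowsums(ad_exp(Svu)),
                  ad_rowsums(ad_mul(ad_exp(Svv), offdiag)))
  loss <- ad_sub(ad_sum(ad_log(denom)), ad_diagsum(Svu))
  loss
}

#' Dual-view contrastive losses for microbes and drugs
#'
#' Symmetric anchoring: each entity's loss is the InfoNCE anchored on its
#' View-1 embeddings plus the InfoNCE anchored on its View-2 embeddings.
#'
#' @param Zm1,Zm2 microbe embeddings from the two views (Nm x d).
#' @param Zd1,Zd2 drug embeddings from the two views (Nd x d).
#' @param head_m,head_d projection heads per entity type.
#' @param tau temperature.
#' @return List with scalar losses `L_cl_m` and `L_cl_d`.
#' @export
dual_contrastive_loss <- function(Zm1, Zm2, Zd1, Zd2,
                                  head_m = NULL, head_d = NULL, tau = 0.5) {
  list(L_cl_m = ad_add(info_nce(Zm1, Zm2, head_m, tau),
                       info_nce(Zm2, Zm1, head_m, tau)),
       L_cl_d = ad_add(info_nce(Zd1, Zd2, head_d, tau),
                       info_nce(Zd2, Zd1, head_d, tau)))
}
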