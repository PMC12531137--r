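# Gaussian interaction profile kernel and non-linear (cross-diffusion)
# fusion of multiple similarity views. Microbes and drugs are symmetric
# cases: for microbes the interaction profiles are the rows of the
# association matrix, for drugs its columns.

#' Gaussian interaction profile (GIP) kernel similarity
#'
#' Similarity between two entities is `exp(-eta * ||p_i - p_j||^2)` where
#' `p_i` is entity i's binary interaction profile (a row or column of the
#' association matrix) and the bandwidth `eta` is the raw bandwidth (1)
#' divided by the mean squared profile norm over all entities.
#'
#' @param A binary association matrix (microbes x drugs).
#' @param axis `"rows"` for microbes, `"columns"` for drugs.
#' @return Symmetric similarity matrix with unit diagonal, values in (0, 1].
#' @examples
#' gip_kernel(diag(2), "rows")[1, 2]  # exp(-2)
#' @export
gip_kernel <- function(A, axis = c("rows", "columns")) {
  axis <- match.arg(axis)
  A <- as.matrix(A)
  P <- if (axis == "rows") A else t(A)
  sq <- rowSums(P^2)
  denom <- mean(sq)
  if (denom == 0) {
    stop("GIP bandwidth denominator is zero: every interaction profile is empty")
  }
  eta <- 1 / denom
  D2 <- outer(sq, sq, "+") - 2 * tcrossprod(P)
  D2[D2 < 0] <- 0
  S <- exp(-eta * D2)
  S <- (S + t(S)) / 2
  diag(S) <- 1
  ids <- if (axis == "rows") rownames(A) else colnames(A)
  if (!is.null(ids)) dimnames(S) <- list(ids, ids)
  S
}

#' Full-kernel weight normalization for similarity fusion
#'
#' Rescales each row so that the diagonal carries weight 1/2 and the
#' off-diagonal entries share the remaining 1/2 proportionally to their
#' similarities: `P(i,j) = S(i,j) / (2 * sum_{k != i} S(i,k))` for `j != i`
#' and `P(i,i) = 1/2`. Every row sums to 1. Rows whose off-diagonal part is
#' all zero keep only the 1/2 diagonal (with a warning).
#'
#' @param S non-negative square matrix.
#' @return Row-normalized matrix.
#' @export
normalize_weights <- function(S) {
  S <- as.matrix(S)
  n <- nrow(S)
  stopifnot(n == ncol(S), n >= 2, min(S) >= 0)
  off <- S
  diag(off) <- 0
  rs <- rowSums(off)
  dead <- rs == 0
  if (any(dead)) {
    warning(sprintf("%d row(s) with all-zero off-diagonal similarity; leaving only the 1/2 diagonal", sum(dead)))
    rs[dead] <- 1  # off-diagonals are all zero, so the quotient is 0 anyway
  }
  P <- off / (2 * rs)
  diag(P) <- 1 / 2
  dimnames(P) <- dimnames(S)
  P
}

# Index sets of the k most-similar neighbours of each row (self excluded),
# ties at the k-th neighbour broken by lowest index.
.knn_index <- function(S, k) {
  n <- nrow(S)
  res <- vapply(seq_len(n), function(i) {
    s <- S[i, ]
    s[i] <- -Inf
    order(-s, seq_len(n))[seq_len(k)]
  }, integer(k))
  if (k == 1L) matrix(res, ncol = 1L) else t(res)
}

#' Local (k-nearest-neighbour) kernel for similarity fusion
#'
#' Keeps, for every entity, only its k most-similar neighbours and
#' renormalizes their similarities to sum to one; all other entries
#' (including the diagonal) are zero.
#'
#' @param S square similarity matrix.
#' @param k neighbour count, `1 <= k <= N - 1`.
#' @return Sparse local affinity kernel, same shape as `S`.
#' @export
local_kernel <- function(S, k) {
  S <- as.matrix(S)
  n <- nrow(S)
  if (k < 1 || k > n - 1) stop("k must be between 1 and N - 1")
  nb <- .knn_index(S, k)
  K <- matrix(0, n, n, dimnames = dimnames(S))
  for (i in seq_len(n)) {
    s <- S[i, nb[i, ]]
    tot <- sum(s)
    if (tot > 0) K[i, nb[i, ]] <- s / tot
  }
  K
}

#' Iterative non-linear fusion of similarity views
#'
#' Cross-diffusion integration of M >= 2 similarity matrices over the same
#' entities. Each view's state is initialized with [normalize_weights()];
#' at every iteration view t is updated to
#' `K_t %*% (mean of the other views' states) %*% t(K_t)` with `K_t` the
#' view's fixed local kernel, then re-normalized. Iteration stops when the
#' largest relative Frobenius change over views drops below `tol`. The final
#' matrix is the symmetrized mean of the per-view states.
#'
#' @param views list of square similarity matrices (same shape).
#' @param k neighbour count of the local kernel; default
#'   `max(1, floor(N/10))`.
#' @param tol relative-change convergence tolerance.
#' @param max_iter iteration cap; non-convergence returns `converged = FALSE`
#'   with a warning.
#' @return An object of class `"fused_similarity"`: list with `S_final`,
#'   `n_iterations`, `converged`.
#' @export
snf_fuse <- function(views, k = NULL, tol = 1e-5, max_iter = 50L) {
  stopifnot(is.list(views), length(views) >= 2)
  dims <- vapply(views, function(v) dim(as.matrix(v)), integer(2))
  if (length(unique(dims[1, ])) != 1 || any(dims[1, ] != dims[2, ])) {
    stop("all views must be square matrices of the same size")
  }
  n <- dims[1, 1]
  if (is.null(k)) k <- max(1L, floor(n / 10))
  M <- length(views)
  P <- lapply(views, normalize_weights)
  K <- lapply(views, local_kernel, k = k)
  converged <- FALSE
  iter <- 0L
  while (iter < max_iter) {
    iter <- iter + 1L
    Pnew <- vector("list", M)
    for (t in seq_len(M)) {
      others <- Reduce(`+`, P[-t]) / (M - 1)
      Pt <- K[[t]] %*% others %*% t(K[[t]])
      Pt[Pt < 0] <- 0
      Pnew[[t]] <- suppressWarnings(normalize_weights(Pt))
    }
    rel <- max(vapply(seq_len(M), function(t) {
      norm(Pnew[[t]] - P[[t]], "F") / max(norm(P[[t]], "F"), .Machine$double.eps)
    }, numeric(1)))
    P <- Pnew
    if (rel < tol) { converged <- TRUE; break }
  }
  if (!converged) warning("similarity fusion did not converge within max_iter")
  S <- Reduce(`+`, P) / M
  S <- (S + t(S)) / 2
  dimnames(S) <- dimnames(as.matrix(views[[1]]))
  structure(list(S_final = S, n_iterations = iter, converged = converged),
            class = "fused_similarity")
}

#' Linear (average) fusion of similarity views
#'
#' Element-wise mean of the views followed by symmetrization; the ablation
#' counterpart of [snf_fuse()].
#'
#' @param views list of square similarity matrices of one shape.
#' @return A `"fused_similarity"` object (`n_iterations = 0`).
#' @export
linear_fuse <- function(views) {
  stopifnot(is.list(views), length(views) >= 1)
  mats <- lapply(views, as.matrix)
  dims <- vapply(mats, dim, integer(2))
  if (length(unique(dims[1, ])) != 1 || any(dims[1, ] != dims[2, ])) {
    stop("all views must be square matrices of the same size")
  }
  S <- Reduce(`+`, mats) / length(mats)
  S <- (S + t(S)) / 2
  structure(list(S_final = S, n_iterations = 0L, converged = TRUE),
            class = "fused_similarity")
}

#' @export
print.fused_similarity <- function(x, ...) {
  cat(sprintf("Fused similarity: %d x %d, %d iteration(s), converged: %s\n",
              nrow(x$S_final), ncol(x$S_final), x$n_iterations, x$converged))
  invisible(x)
}
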