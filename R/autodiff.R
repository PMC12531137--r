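# Minimal reverse-mode automatic differentiation on dense matrices.
#
# Every quantity is a numeric matrix (scalars are 1x1). Operations accept a
# mix of tape nodes and plain matrices; when no argument is a node the plain
# numeric result is returned, so the same forward code serves both training
# (with gradients) and inference/testing (without).

ad_tape <- function() {
  t <- new.env(parent = emptyenv())
  t$nodes <- vector("list", 512L)
  t$n <- 0L
  t
}

is_adnode <- function(x) inherits(x, "adnode")

ad_val <- function(x) if (is_adnode(x)) x$val else x

.ad_new <- function(tape, val, parents = list(), backfn = NULL) {
  n <- new.env(parent = emptyenv())
  n$val <- val
  n$grad <- NULL
  n$parents <- parents
  n$backfn <- backfn
  n$tape <- tape
  class(n) <- "adnode"
  if (!is.null(tape) && !is.null(backfn)) {
    tape$n <- tape$n + 1L
    if (tape$n > length(tape$nodes)) {
      tape$nodes <- c(tape$nodes, vector("list", length(tape$nodes)))
    }
    tape$nodes[[tape$n]] <- n
  }
  n
}

#' Create a differentiable leaf (parameter) on a tape
#' @param tape a tape from `ad_tape()`
#' @param val numeric matrix
#' @keywords internal
#' @noRd
ad_leaf <- function(tape, val) .ad_new(tape, as.matrix(val))

# Build an op node if any argument is a node; otherwise pass the value through.
.ad_make <- function(args, val, backfn) {
  is_node <- vapply(args, is_adnode, logical(1))
  if (!any(is_node)) return(val)
  tape <- args[[which(is_node)[1L]]]$tape
  .ad_new(tape, val, parents = args, backfn = backfn)
}

.acc <- function(node, g) {
  if (is.null(node$grad)) node$grad <- g else node$grad <- node$grad + g
}

# Run backpropagation from a scalar loss node. After the call every leaf
# reachable from `loss` carries its gradient in `$grad`.
ad_backward <- function(loss) {
  stopifnot(is_adnode(loss), length(loss$val) == 1L)
  tape <- loss$tape
  loss$grad <- matrix(1, 1L, 1L)
  for (i in rev(seq_len(tape$n))) {
    node <- tape$nodes[[i]]
    if (is.null(node$grad) || is.null(node$backfn)) next
    grads <- node$backfn(node$grad)
    for (j in seq_along(node$parents)) {
      p <- node$parents[[j]]
      if (is_adnode(p) && !is.null(grads[[j]])) .acc(p, grads[[j]])
    }
  }
  invisible(loss)
}

# ---- primitive operations ----------------------------------------------

ad_matmul <- function(a, b) {
  A <- ad_val(a); B <- ad_val(b)
  .ad_make(list(a, b), A %*% B, function(G) {
    list(if (is_adnode(a)) G %*% t(B) else NULL,
         if (is_adnode(b)) t(A) %*% G else NULL)
  })
}

ad_add <- function(a, b) {
  .ad_make(list(a, b), ad_val(a) + ad_val(b), function(G) list(G, G))
}

ad_sub <- function(a, b) {
  .ad_make(list(a, b), ad_val(a) - ad_val(b), function(G) list(G, -G))
}

ad_mul <- function(a, b) {
  A <- ad_val(a); B <- ad_val(b)
  .ad_make(list(a, b), A * B, function(G) {
    list(if (is_adnode(a)) G * B else NULL,
         if (is_adnode(b)) G * A else NULL)
  })
}

ad_div <- function(a, b) {
  A <- ad_val(a); B <- ad_val(b)
  .ad_make(list(a, b), A / B, function(G) {
    list(if (is_adnode(a)) G / B else NULL,
         if (is_adnode(b)) -G * A / (B * B) else NULL)
  })
}

ad_scale <- function(a, s) {
  .ad_make(list(a), s * ad_val(a), function(G) list(s * G))
}

ad_shift <- function(a, c) {
  .ad_make(list(a), ad_val(a) + c, function(G) list(G))
}

# X (n x d) plus a 1 x d bias row broadcast over rows.
ad_add_bias <- function(x, b) {
  X <- ad_val(x); bv <- as.vector(ad_val(b))
  val <- X + rep(1, nrow(X)) %o% bv
  .ad_make(list(x, b), val, function(G) {
    list(G, if (is_adnode(b)) matrix(colSums(G), 1L) else NULL)
  })
}

ad_relu <- function(a) {
  A <- ad_val(a)
  .ad_make(list(a), pmax(A, 0), function(G) list(G * (A > 0)))
}

ad_elu <- function(a) {
  A <- ad_val(a)
  val <- ifelse(A > 0, A, exp(A) - 1)
  .ad_make(list(a), val, function(G) list(G * ifelse(A > 0, 1, val + 1)))
}

ad_sigmoid <- function(a) {
  s <- 1 / (1 + exp(-ad_val(a)))
  .ad_make(list(a), s, function(G) list(G * s * (1 - s)))
}

ad_exp <- function(a) {
  v <- exp(ad_val(a))
  .ad_make(list(a), v, function(G) list(G * v))
}

ad_log <- function(a) {
  A <- ad_val(a)
  .ad_make(list(a), log(A), function(G) list(G / A))
}

ad_sqrt <- function(a) {
  v <- sqrt(ad_val(a))
  .ad_make(list(a), v, function(G) list(G / (2 * v)))
}

ad_sum <- function(a) {
  A <- ad_val(a)
  .ad_make(list(a), matrix(sum(A), 1L, 1L), function(G) {
    list(matrix(G[1L], nrow(A), ncol(A)))
  })
}

ad_rowsums <- function(a) {
  A <- ad_val(a)
  .ad_make(list(a), matrix(rowSums(A), ncol = 1L), function(G) {
    list(G %*% matrix(1, 1L, ncol(A)))
  })
}

ad_colmeans <- function(a) {
  A <- ad_val(a)
  .ad_make(list(a), matrix(colMeans(A), 1L), function(G) {
    list(rep(1, nrow(A)) %o% as.vector(G) / nrow(A))
  })
}

# Row sums over a fixed subset of columns -> n x 1.
ad_rowsums_cols <- function(a, cols) {
  A <- ad_val(a)
  .ad_make(list(a), matrix(rowSums(A[, cols, drop = FALSE]), ncol = 1L),
           function(G) {
    Z <- matrix(0, nrow(A), ncol(A))
    Z[, cols] <- G %*% matrix(1, 1L, length(cols))
    list(Z)
  })
}

# Multiply each row i of M (n x d) by scalar v[i] (v is n x 1).
ad_colbroadcast_mul <- function(v, m) {
  V <- as.vector(ad_val(v)); M <- ad_val(m)
  .ad_make(list(v, m), M * V, function(G) {
    list(if (is_adnode(v)) matrix(rowSums(G * M), ncol = 1L) else NULL,
         if (is_adnode(m)) G * V else NULL)
  })
}

# Multiply each column j of M (n x d) by scalar g[j] (g is 1 x d).
ad_rowbroadcast_mul <- function(g, m) {
  gv <- as.vector(ad_val(g)); M <- ad_val(m)
  ones <- rep(1, nrow(M))
  val <- M * (ones %o% gv)
  .ad_make(list(g, m), val, function(G) {
    list(if (is_adnode(g)) matrix(colSums(G * M), 1L) else NULL,
         if (is_adnode(m)) G * (ones %o% gv) else NULL)
  })
}

ad_transpose <- function(a) {
  .ad_make(list(a), t(ad_val(a)), function(G) list(t(G)))
}

ad_hcat <- function(a, b) {
  A <- ad_val(a); B <- ad_val(b)
  .ad_make(list(a, b), cbind(A, B), function(G) {
    list(G[, seq_len(ncol(A)), drop = FALSE],
         G[, ncol(A) + seq_len(ncol(B)), drop = FALSE])
  })
}

ad_diagsum <- function(a) {
  A <- ad_val(a)
  .ad_make(list(a), matrix(sum(diag(A)), 1L, 1L), function(G) {
    list(diag(G[1L], nrow(A), ncol(A)))
  })
}

# Column-wise softmax restricted to mask == 1 (mask is a plain binary matrix
# with at least one 1 per column); entries outside the mask get weight 0.
ad_masked_softmax_cols <- function(scores, mask) {
  S <- ad_val(scores)
  SS <- S
  SS[mask == 0] <- -Inf
  mx <- apply(SS, 2L, max)
  E <- exp(SS - rep(1, nrow(S)) %o% mx)
  E[mask == 0] <- 0
  cs <- colSums(E)
  val <- E / (rep(1, nrow(S)) %o% cs)
  .ad_make(list(scores), val, function(G) {
    cg <- colSums(G * val)
    list(val * (G - rep(1, nrow(S)) %o% cg))
  })
}

# Literal ratio normalization of scores within each column's mask.
ad_masked_ratio_cols <- function(scores, mask) {
  S <- ad_val(scores)
  q <- colSums(S * mask)
  ones <- rep(1, nrow(S))
  val <- (S * mask) / (ones %o% q)
  .ad_make(list(scores), val, function(G) {
    cg <- colSums(G * val)
    list(mask * (G - ones %o% cg) / (ones %o% q))
  })
}

# ---- parameter containers and Adam -------------------------------------

# Recursively apply f to every matrix in a nested list of parameters.
param_map <- function(x, f) {
  if (is.list(x)) lapply(x, param_map, f = f) else f(x)
}

# Parallel recursion over two identically shaped nested lists.
param_map2 <- function(x, y, f) {
  if (is.list(x)) {
    out <- vector("list", length(x))
    names(out) <- names(x)
    for (i in seq_along(x)) out[[i]] <- param_map2(x[[i]], y[[i]], f)
    out
  } else {
    f(x, y)
  }
}

# Wrap a nested parameter list as tape leaves.
params_to_leaves <- function(tape, params) {
  param_map(params, function(w) ad_leaf(tape, w))
}

# Extract gradients from leaves (zero where a parameter was unused).
leaves_to_grads <- function(leaves) {
  param_map(leaves, function(n) {
    if (is.null(n$grad)) matrix(0, nrow(n$val), ncol(n$val)) else n$grad
  })
}

adam_init <- function(params) {
  list(m = param_map(params, function(w) w * 0),
       v = param_map(params, function(w) w * 0),
       t = 0L)
}

adam_step <- function(params, grads, state, lr,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  state$m <- param_map2(state$m, grads, function(m, g) beta1 * m + (1 - beta1) * g)
  state$v <- param_map2(state$v, grads, function(v, g) beta2 * v + (1 - beta2) * g * g)
  c1 <- 1 - beta1^state$t
  c2 <- 1 - beta2^state$t
  mv <- param_map2(state$m, state$v, function(m, v) {
    (m / c1) / (sqrt(v / c2) + eps)
  })
  params <- param_map2(params, mv, function(w, d) w - lr * d)
  list(params = params, state = state)
}

# Glorot-uniform initialization for a fan_in x fan_out matrix.
glorot <- function(fan_in, fan_out) {
  a <- sqrt(6 / (fan_in + fan_out))
  matrix(stats::runif(fan_in * fan_out, -a, a), fan_in, fan_out)
}
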