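# Node feature assembly and construction of the two hypergraph views per
# entity type: a k-nearest-neighbour view (one hyperedge per node) and a
# clustering view (one hyperedge per cluster centre).

#' Build node feature matrices
#'
#' Node features concatenate the entity's association profile with its row
#' of the fused similarity matrix: microbe i's feature vector is
#' `[A(i, ), S_final(i, )]` (length Nd + Nm); drug j's is
#' `[A(, j), DS_final(j, )]` (length Nm + Nd).
#'
#' @param A association matrix (microbes x drugs).
#' @param fused a `"fused_similarity"` object or square matrix for the
#'   requested entity.
#' @param entity `"microbe"` or `"drug"`.
#' @return Feature matrix (N x F).
#' @export
build_node_features <- function(A, fused, entity = c("microbe", "drug")) {
  entity <- match.arg(entity)
  A <- as.matrix(A)
  S <- if (inherits(fused, "fused_similarity")) fused$S_final else as.matrix(fused)
  if (entity == "microbe") {
    if (nrow(S) != nrow(A)) stop("fused microbe similarity does not match the association matrix")
    cbind(A, S)
  } else {
    if (nrow(S) != ncol(A)) stop("fused drug similarity does not match the association matrix")
    cbind(t(A), S)
  }
}

# Internal constructor: validate incidence and compute degrees.
new_hypergraph <- function(H, view_tag, w = NULL) {
  H <- as.matrix(H)
  if (anyNA(H) || !all(H %in% c(0, 1))) stop("incidence matrix must be binary")
  if (any(colSums(H) == 0)) stop("empty hyperedge in incidence matrix")
  if (is.null(w)) w <- rep(1, ncol(H))
  d_v <- as.vector(H %*% w)
  d_e <- colSums(H)
  iso <- which(d_v == 0)
  if (length(iso)) stop("isolated node(s) with zero hyperedge degree: ",
                        paste(iso, collapse = ", "))
  structure(list(H = H, W = w, d_v = d_v, d_e = d_e, view_tag = view_tag),
            class = "hypergraph")
}

#' @export
print.hypergraph <- function(x, ...) {
  cat(sprintf("Hypergraph (%s): %d nodes, %d hyperedges, mean hyperedge size %.2f\n",
              x$view_tag, nrow(x$H), ncol(x$H), mean(x$d_e)))
  invisible(x)
}

#' Node and hyperedge degree vectors
#'
#' `d(e) = sum_v H(v, e)` and `d(v) = sum_e w(e) H(v, e)`; both must be
#' strictly positive (no empty hyperedge, no isolated node).
#'
#' @param hg a `"hypergraph"`.
#' @return List with numeric vectors `d_v` and `d_e`.
#' @export
degree_matrices <- function(hg) {
  stopifnot(inherits(hg, "hypergraph"))
  d_e <- colSums(hg$H)
  d_v <- as.vector(hg$H %*% hg$W)
  iso <- which(d_v == 0)
  if (length(iso)) stop("isolated node(s): ", paste(iso, collapse = ", "))
  if (any(d_e == 0)) stop("empty hyperedge")
  list(d_v = d_v, d_e = d_e)
}

# Pairwise squared Euclidean distances between rows of X.
.sqdist <- function(X) {
  sq <- rowSums(X^2)
  D2 <- outer(sq, sq, "+") - 2 * tcrossprod(X)
  D2[D2 < 0] <- 0
  D2
}

#' K-nearest-neighbour hypergraph (View 1)
#'
#' One hyperedge per node: hyperedge i joins node i (when
#' `include_centroid`) with its k nearest neighbours in Euclidean distance
#' on the feature rows. Ties are broken by lowest index.
#'
#' @param X feature matrix (N x F).
#' @param k neighbour count, `1 <= k <= N - 1`.
#' @param include_centroid keep node i inside its own hyperedge (default).
#' @return A `"hypergraph"` with N hyperedges, tagged `"View1"`.
#' @export
knn_hypergraph <- function(X, k, include_centroid = TRUE) {
  X <- as.matrix(X)
  n <- nrow(X)
  if (k < 1 || k > n - 1) stop("k must be between 1 and N - 1")
  D2 <- .sqdist(X)
  diag(D2) <- Inf
  H <- matrix(0, n, n)
  for (i in seq_len(n)) {
    nb <- order(D2[i, ], seq_len(n))[seq_len(k)]
    H[nb, i] <- 1
    if (include_centroid) H[i, i] <- 1
  }
  new_hypergraph(H, "View1")
}

# Squared distances from rows of X to rows of centres C.
.sqdist_to <- function(X, C) {
  D2 <- outer(rowSums(X^2), rowSums(C^2), "+") - 2 * tcrossprod(X, C)
  D2[D2 < 0] <- 0
  D2
}

# k-means++-style seeded initialization of c centres from rows of X.
.kmpp_init <- function(X, c) {
  n <- nrow(X)
  centres <- numeric(c)
  centres[1] <- sample.int(n, 1L)
  d2 <- .sqdist_to(X, X[centres[1], , drop = FALSE])[, 1]
  for (j in seq_len(c - 1L)) {
    p <- if (sum(d2) > 0) d2 / sum(d2) else rep(1 / n, n)
    centres[j + 1L] <- sample.int(n, 1L, prob = p)
    d2 <- pmin(d2, .sqdist_to(X, X[centres[j + 1L], , drop = FALSE])[, 1])
  }
  X[centres, , drop = FALSE]
}

# One Lloyd step; returns updated centres with empty clusters repaired by
# stealing the farthest point of the largest cluster.
.lloyd_step <- function(X, C) {
  D2 <- .sqdist_to(X, C)
  assign <- max.col(-D2, ties.method = "first")
  for (j in seq_len(nrow(C))) {
    members <- which(assign == j)
    if (!length(members)) {
      big <- which.max(tabulate(assign, nbins = nrow(C)))
      cand <- which(assign == big)
      far <- cand[which.max(D2[cbind(cand, big)])]
      assign[far] <- j
      members <- far
    }
    C[j, ] <- colMeans(X[members, , drop = FALSE])
  }
  C
}

.fitness <- function(X, C) sum(apply(.sqdist_to(X, C), 1L, min))

#' Clustering (KO) hypergraph (View 2)
#'
#' One hyperedge per cluster: nodes are partitioned into `c` clusters by a
#' seeded population-based refinement of K-means. A population of candidate
#' centre sets (k-means++-style initialization) is advanced one Lloyd step
#' per iteration; every candidate is then pulled a step towards the centroid
#' of the top-quartile candidates by within-cluster fitness (the sum of
#' squared distances of each node to its nearest centre). The best candidate
#' ever seen is the answer; iteration stops early once it has not improved.
#' Each node joins exactly one hyperedge (its nearest final centre); empty
#' clusters are repaired by reassigning the farthest point from the largest
#' cluster.
#'
#' @param X feature matrix (N x F).
#' @param c number of clusters, `2 <= c <= N`.
#' @param pop_size candidate population size.
#' @param max_iter iteration cap.
#' @param seed integer seed; the construction is deterministic given it.
#' @param step pull factor towards the elite centroid.
#' @return A `"hypergraph"` with `c` hyperedges, tagged `"View2"`.
#' @export
ko_hypergraph <- function(X, c, pop_size = 10L, max_iter = 100L, seed = 1L,
                          step = 0.5) {
  X <- as.matrix(X)
  n <- nrow(X)
  if (c < 2 || c > n) stop("cluster count c must be between 2 and N")
  withr::with_seed(seed, {
    pop <- replicate(pop_size, .kmpp_init(X, c), simplify = FALSE)
    best <- pop[[1]]
    best_fit <- .fitness(X, best)
    stall <- 0L
    for (iter in seq_len(max_iter)) {
      pop <- lapply(pop, function(C) .lloyd_step(X, C))
      fits <- vapply(pop, function(C) .fitness(X, C), numeric(1))
      improved <- min(fits) < best_fit - 1e-12
      if (improved) {
        best_fit <- min(fits)
        best <- pop[[which.min(fits)]]
        stall <- 0L
      } else {
        stall <- stall + 1L
      }
      if (stall >= 3L) break
      elite <- pop[order(fits)[seq_len(max(1L, floor(pop_size / 4)))]]
      elite_mean <- Reduce(`+`, elite) / length(elite)
      pop <- lapply(pop, function(C) C + step * (elite_mean - C))
    }
  })
  D2 <- .sqdist_to(X, best)
  assign <- max.col(-D2, ties.method = "first")
  for (j in seq_len(c)) {
    if (!any(assign == j)) {
      big <- which.max(tabulate(assign, nbins = c))
      cand <- which(assign == big)
      far <- cand[which.max(D2[cbind(cand, big)])]
      assign[far] <- j
    }
  }
  H <- matrix(0, n, c)
  H[cbind(seq_len(n), assign)] <- 1
  new_hypergraph(H, "View2")
}

#' Serialize a hypergraph to a two-column (node, hyperedge) TSV
#' @param hg a `"hypergraph"`.
#' @param path output path.
#' @export
write_hypergraph <- function(hg, path) {
  idx <- which(hg$H == 1, arr.ind = TRUE)
  writeLines(sprintf("%d\t%d", idx[, 1], idx[, 2]), path)
  invisible(path)
}
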