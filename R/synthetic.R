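# Seeded synthetic-data generator. Plants a block-structured low-rank
# latent model: entities fall into blocks in latent space (so both the
# nearest-neighbour and the clustering hypergraph views have structure to
# find), association probabilities are a monotone squashing of the latent
# inner products calibrated to a target density, and the similarity views
# are noisy, partially-missing cosine similarities of the latent factors.

#' Specification for a synthetic dataset
#'
#' Defaults describe the desk-scale study conditions used throughout the
#' package tests: 60 microbes x 120 drugs, rank-4 latent factors in 3
#' blocks, 5% association density (within the density regime of the public
#' microbe-drug databases), similarity noise SD 0.05 and half of the
#' external-similarity entries missing (those matrices are sparse in
#' practice).
#'
#' @param n_microbes,n_drugs entity counts.
#' @param latent_rank rank of the planted factors.
#' @param n_blocks number of latent blocks per entity type.
#' @param target_density expected fraction of positive associations, in
#'   (0, 1).
#' @param similarity_noise_sd SD of the truncated Gaussian noise added to
#'   the similarity views.
#' @param ms1_missing_frac fraction of off-diagonal similarity pairs zeroed
#'   (symmetrically) in the external views, in \[0, 1).
#' @param logit_sd scale of the association logits: the latent inner
#'   products are standardized and multiplied by this value before the
#'   density-calibrating bias is added. It sets the signal-to-noise of the
#'   Bernoulli sampling — the SD of the Gaussian logits behind the planted
#'   associations — and hence how recoverable the planted structure is; the
#'   default of 3 makes an oracle scoring by the true logits nearly
#'   perfect, emulating the strongly predictable regime of the curated
#'   association databases.
#' @param seed integer seed; every draw flows through it.
#' @return An object of class `"synthetic_spec"`.
#' @export
synthetic_spec <- function(n_microbes = 60L, n_drugs = 120L, latent_rank = 4L,
                           n_blocks = 3L, target_density = 0.05,
                           similarity_noise_sd = 0.05,
                           ms1_missing_frac = 0.5, logit_sd = 3,
                           seed = 0L) {
  spec <- list(n_microbes = as.integer(n_microbes),
               n_drugs = as.integer(n_drugs),
               latent_rank = as.integer(latent_rank),
               n_blocks = as.integer(n_blocks),
               target_density = target_density,
               similarity_noise_sd = similarity_noise_sd,
               ms1_missing_frac = ms1_missing_frac,
               logit_sd = logit_sd,
               seed = as.integer(seed))
  stopifnot(spec$n_microbes > 0, spec$n_drugs > 0, spec$latent_rank >= 1,
            spec$n_blocks >= 1, spec$target_density > 0,
            spec$target_density < 1, spec$similarity_noise_sd >= 0,
            spec$ms1_missing_frac >= 0, spec$ms1_missing_frac < 1,
            spec$logit_sd > 0)
  if (spec$target_density < 1 / (spec$n_microbes * spec$n_drugs)) {
    stop("target density below one association in the whole matrix")
  }
  structure(spec, class = "synthetic_spec")
}

# Block-structured latent factors: block centres plus member jitter.
.block_factors <- function(n, r, n_blocks, centre_sd = 2, jitter_sd = 0.5) {
  blocks <- rep_len(seq_len(n_blocks), n)
  centres <- matrix(stats::rnorm(n_blocks * r, sd = centre_sd), n_blocks, r)
  U <- centres[blocks, , drop = FALSE] +
    matrix(stats::rnorm(n * r, sd = jitter_sd), n, r)
  list(U = U, blocks = blocks)
}

# Cosine similarity of rows rescaled to [0, 1], noised, with a fixed count
# of off-diagonal pairs zeroed symmetrically.
.latent_similarity <- function(U, noise_sd, missing_frac) {
  n <- nrow(U)
  nrm <- sqrt(rowSums(U^2)) + 1e-12
  S <- tcrossprod(U / nrm)
  S <- (S + 1) / 2
  if (noise_sd > 0) {
    E <- matrix(0, n, n)
    E[upper.tri(E)] <- stats::rnorm(n * (n - 1) / 2, sd = noise_sd)
    S <- S + E + t(E)
  }
  S <- pmin(pmax(S, 0), 1)
  diag(S) <- 1
  n_zero <- floor(missing_frac * n * (n - 1) / 2)
  if (n_zero > 0) {
    pairs <- which(upper.tri(S), arr.ind = TRUE)
    drop <- pairs[sample.int(nrow(pairs), n_zero), , drop = FALSE]
    S[drop] <- 0
    S[drop[, c(2, 1), drop = FALSE]] <- 0
  }
  S
}

# Solve the bias of sigmoid(UV' + b) so the expected density hits target.
.solve_bias <- function(M, target, lo = -50, hi = 50) {
  f <- function(b) mean(1 / (1 + exp(-(M + b)))) - target
  if (f(lo) > 0 || f(hi) < 0) stop("target density unreachable by bias search")
  stats::uniroot(f, c(lo, hi), tol = 1e-10)$root
}

#' Generate a synthetic association dataset
#'
#' @param spec a [synthetic_spec()].
#' @return An object of class `"mda_synth"`: list with `ds` (an
#'   [mda_dataset()]), similarity views `ms1` and `ds1`, the planted `truth`
#'   (factors and block labels) and the generating specification.
#' @examples
#' sd <- generate_dataset(synthetic_spec(seed = 1))
#' dataset_summary(sd$ds)
#' @export
generate_dataset <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  withr::with_seed(spec$seed, {
    fm <- .block_factors(spec$n_microbes, spec$latent_rank, spec$n_blocks)
    fd <- .block_factors(spec$n_drugs, spec$latent_rank, spec$n_blocks)
    M <- tcrossprod(fm$U, fd$U)
    M <- M / stats::sd(M) * spec$logit_sd
    b <- .solve_bias(M, spec$target_density)
    P <- 1 / (1 + exp(-(M + b)))
    A <- matrix(stats::rbinom(length(P), 1L, as.vector(P)),
                nrow(P), ncol(P))
    ms1 <- .latent_similarity(fm$U, spec$similarity_noise_sd,
                              spec$ms1_missing_frac)
    ds1 <- .latent_similarity(fd$U, spec$similarity_noise_sd,
                              spec$ms1_missing_frac)
  })
  ids_m <- sprintf("m%03d", seq_len(spec$n_microbes))
  ids_d <- sprintf("d%03d", seq_len(spec$n_drugs))
  dimnames(ms1) <- list(ids_m, ids_m)
  dimnames(ds1) <- list(ids_d, ids_d)
  structure(list(ds = mda_dataset(A, ids_m, ids_d),
                 ms1 = ms1, ds1 = ds1,
                 truth = list(U = fm$U, V = fd$U,
                              microbe_blocks = fm$blocks,
                              drug_blocks = fd$blocks),
                 spec = spec),
            class = "mda_synth")
}

#' @export
print.mda_synth <- function(x, ...) {
  s <- dataset_summary(x$ds)
  cat(sprintf("Synthetic dataset: %d x %d, density %.2f%% (target %.2f%%), rank %d, %d blocks, seed %d\n",
              s$n_microbes, s$n_drugs, s$density_percent,
              100 * x$spec$target_density, x$spec$latent_rank,
              x$spec$n_blocks, x$spec$seed))
  invisible(x)
}

#' Permute association labels (null control)
#'
#' Randomly permutes the entries of the association matrix (preserving the
#' number of positives exactly) while leaving the similarity views
#' untouched, destroying the linkage between associations and the planted
#' latent structure.
#'
#' @param sd an `"mda_synth"` object.
#' @param seed integer seed for the permutation.
#' @return A copy with permuted `ds`.
#' @export
permute_labels <- function(sd, seed = 0L) {
  stopifnot(inherits(sd, "mda_synth"))
  A <- sd$ds$A
  perm <- withr::with_seed(seed, sample.int(length(A)))
  Ap <- matrix(as.vector(A)[perm], nrow(A), ncol(A),
               dimnames = dimnames(A))
  out <- sd
  out$ds <- mda_dataset(Ap, sd$ds$microbe_ids, sd$ds$drug_ids)
  out$permuted <- TRUE
  out
}

#' Write a synthetic dataset to a directory
#'
#' Writes `association.tsv` (dense), `ms1.tsv` and `ds1.tsv` in the
#' package's TSV conventions.
#'
#' @param sd an `"mda_synth"` object.
#' @param dir output directory (created if needed).
#' @export
write_synthetic <- function(sd, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_association(sd$ds, file.path(dir, "association.tsv"), "dense")
  write_similarity(sd$ms1, file.path(dir, "ms1.tsv"))
  write_similarity(sd$ds1, file.path(dir, "ds1.tsv"))
  invisible(dir)
}
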