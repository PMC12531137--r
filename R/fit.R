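# Model fitting: assembles the full forward graph -- interaction-profile
# kernels on the (fold-masked) association matrix, similarity fusion,
# feature building, two hypergraph views per entity, hierarchical attention
# + hypergraph convolution, dual-view contrastive loss, gating + inter-view
# fusion, decoding and the weighted reconstruction loss -- and optimizes all
# parameters with Adam.

# Build everything that does not depend on the learnable parameters.
build_model_cache <- function(ds, ms1, ds1, cfg, exclude = NULL) {
  A_full <- ds$A
  nm <- nrow(A_full); nd <- ncol(A_full)
  excl <- matrix(0, nm, nd)
  if (!is.null(exclude) && nrow(exclude) > 0) {
    excl[cbind(exclude[, 1], exclude[, 2])] <- 1
  }
  A_train <- A_full * (1 - excl)   # held-out positives are hidden entirely

  fuse_entity <- function(ext, gipS, n) {
    views <- switch(cfg$similarity_views,
      both = if (is.null(ext)) list(gipS) else list(ext, gipS),
      external = {
        if (is.null(ext)) stop("similarity_views = 'external' but no external similarity supplied")
        list(ext)
      },
      gip = list(gipS))
    if (length(views) >= 2) {
      if (cfg$fusion == "snf") {
        snf_fuse(views, k = cfg$snf_k, tol = cfg$snf_tol,
                 max_iter = cfg$snf_max_iter)
      } else {
        linear_fuse(views)
      }
    } else {
      structure(list(S_final = (views[[1]] + t(views[[1]])) / 2,
                     n_iterations = 0L, converged = TRUE),
                class = "fused_similarity")
    }
  }

  MS2 <- gip_kernel(A_train, "rows")
  DS2 <- gip_kernel(A_train, "columns")
  fused_m <- fuse_entity(ms1, MS2, nm)
  fused_d <- fuse_entity(ds1, DS2, nd)

  Xm <- build_node_features(A_train, fused_m, "microbe")
  Xd <- build_node_features(A_train, fused_d, "drug")

  km <- min(cfg$knn_k, nm - 1L)
  kd <- min(cfg$knn_k, nd - 1L)
  cm <- min(cfg$ko_c, nm)
  cd <- min(cfg$ko_c, nd)
  hg_m1 <- knn_hypergraph(Xm, km, cfg$include_centroid)
  hg_d1 <- knn_hypergraph(Xd, kd, cfg$include_centroid)
  hg_m2 <- ko_hypergraph(Xm, cm, cfg$ko_pop_size, cfg$ko_max_iter,
                         seed = cfg$seed + 101L)
  hg_d2 <- ko_hypergraph(Xd, cd, cfg$ko_pop_size, cfg$ko_max_iter,
                         seed = cfg$seed + 202L)

  obs <- (A_train == 1) * (1 - excl)
  unobs <- (A_train == 0) * (1 - excl)

  list(A_full = A_full, A_train = A_train, excl = excl,
       obs = obs, unobs = unobs,
       fused_m = fused_m, fused_d = fused_d,
       Xm = Xm, Xd = Xd,
       hg_m1 = hg_m1, hg_m2 = hg_m2, hg_d1 = hg_d1, hg_d2 = hg_d2)
}

init_model_params <- function(cache, cfg) {
  d <- cfg$embed_dim
  L <- cfg$hgcn_layers
  withr::with_seed(cfg$seed, {
    list(enc_m1 = init_encoder_params(ncol(cache$Xm), d, L),
         enc_m2 = init_encoder_params(ncol(cache$Xm), d, L),
         enc_d1 = init_encoder_params(ncol(cache$Xd), d, L),
         enc_d2 = init_encoder_params(ncol(cache$Xd), d, L),
         head_m = init_projection_head(d),
         head_d = init_projection_head(d),
         int_m = init_integration_params(d),
         int_d = init_integration_params(d))
  })
}

# One forward pass; params may be plain matrices or tape leaves.
model_forward <- function(cache, params, cfg) {
  norm <- cfg$attention_norm
  Zm1 <- encode_view(cache$hg_m1, cache$Xm, params$enc_m1, norm, cfg$use_dha)
  Zm2 <- encode_view(cache$hg_m2, cache$Xm, params$enc_m2, norm, cfg$use_dha)
  Zd1 <- encode_view(cache$hg_d1, cache$Xd, params$enc_d1, norm, cfg$use_dha)
  Zd2 <- encode_view(cache$hg_d2, cache$Xd, params$enc_d2, norm, cfg$use_dha)

  if (cfg$use_cl && (cfg$lambda_m != 0 || cfg$gamma_d != 0)) {
    cl <- dual_contrastive_loss(Zm1, Zm2, Zd1, Zd2,
                                params$head_m, params$head_d, cfg$tau)
  } else {
    cl <- list(L_cl_m = matrix(0, 1L, 1L), L_cl_d = matrix(0, 1L, 1L))
  }

  Gm1 <- view_gate(Zm1, params$int_m$gate_v1)
  Gm2 <- view_gate(Zm2, params$int_m$gate_v2)
  Gd1 <- view_gate(Zd1, params$int_d$gate_v1)
  Gd2 <- view_gate(Zd2, params$int_d$gate_v2)

  Hm <- interview_attention(Gm1, Gm2, params$int_m, cfg$n_heads)
  Hd <- interview_attention(Gd1, Gd2, params$int_d, cfg$n_heads)

  As <- decode_scores(Hm, Hd, params$int_m, params$int_d)
  L_RE <- reconstruction_loss(cache$A_train, As, cache$obs, cache$unobs,
                              cfg$alpha)
  loss <- total_loss(L_RE, cl$L_cl_m, cl$L_cl_d, cfg$lambda_m, cfg$gamma_d)
  list(As = As, L_RE = L_RE, L_cl_m = cl$L_cl_m, L_cl_d = cl$L_cl_d,
       loss = loss)
}

#' Fit the dual-hypergraph association model
#'
#' Trains the full model on an association dataset: Gaussian
#' interaction-profile kernels are computed from the (optionally
#' fold-masked) association matrix and fused with any supplied external
#' similarities; node features feed two hypergraph views per entity type,
#' each encoded by hierarchical attention and hypergraph convolution; the
#' views are tied by a dual-view InfoNCE loss, gated, fused by multi-head
#' inter-view attention and decoded into association scores; all parameters
#' are optimized with Adam against the weighted Frobenius reconstruction
#' loss plus the contrastive terms.
#'
#' @param ds an [mda_dataset()].
#' @param ms1 optional external microbe (functional) similarity matrix.
#' @param ds1 optional external drug (structural) similarity matrix.
#' @param config an [mda_config()].
#' @param exclude optional two-column matrix of (microbe index, drug index)
#'   pairs to hold out: their labels are hidden from the kernels and from
#'   both reconstruction masks (neither observed nor unobserved).
#' @return An object of class `"hypermda"` with components `params`,
#'   `config`, `loss_trace`, `scores` (the fitted score matrix), `cache`
#'   (fixed model inputs) and the identifier lists.
#' @examples
#' sd <- generate_dataset(synthetic_spec(n_microbes = 15, n_drugs = 20,
#'                                       target_density = 0.2, seed = 7))
#' cfg <- mda_config(embed_dim = 10, n_heads = 2, epochs = 3, knn_k = 3,
#'                   ko_c = 3, seed = 7)
#' fit <- hypermda(sd$ds, sd$ms1, sd$ds1, cfg)
#' print(fit)
#' @export
hypermda <- function(ds, ms1 = NULL, ds1 = NULL, config = mda_config(),
                     exclude = NULL) {
  stopifnot(inherits(ds, "mda_dataset"), inherits(config, "mda_config"))
  log_msg(config, "fitting hypermda: %d microbes x %d drugs, %d epochs, d = %d",
          nrow(ds$A), ncol(ds$A), config$epochs, config$embed_dim)
  cache <- build_model_cache(ds, ms1, ds1, config, exclude)
  params <- init_model_params(cache, config)
  state <- adam_init(params)
  trace <- numeric(config$epochs)
  for (epoch in seq_len(config$epochs)) {
    tape <- ad_tape()
    leaves <- params_to_leaves(tape, params)
    fw <- model_forward(cache, leaves, config)
    lv <- ad_val(fw$loss)[1L]
    if (!is.finite(lv)) {
      stop(sprintf("non-finite training loss (%g) at epoch %d", lv, epoch))
    }
    trace[epoch] <- lv
    ad_backward(fw$loss)
    grads <- leaves_to_grads(leaves)
    upd <- adam_step(params, grads, state, config$learning_rate)
    params <- upd$params
    state <- upd$state
    if (epoch %% 50L == 0L) log_msg(config, "  epoch %d: loss %.4f", epoch, lv)
  }
  final <- model_forward(cache, params, config)
  structure(list(params = params, config = config,
                 loss_trace = trace, scores = final$As,
                 final_losses = list(total = ad_val(final$loss)[1L],
                                     reconstruction = ad_val(final$L_RE)[1L],
                                     contrastive_m = ad_val(final$L_cl_m)[1L],
                                     contrastive_d = ad_val(final$L_cl_d)[1L]),
                 cache = cache,
                 microbe_ids = ds$microbe_ids, drug_ids = ds$drug_ids),
            class = "hypermda")
}

n_parameters <- function(params) {
  tot <- 0L
  param_map(params, function(w) { tot <<- tot + length(w); w })
  tot
}

#' @export
print.hypermda <- function(x, ...) {
  cat(sprintf("Dual-hypergraph association model: %d microbes x %d drugs\n",
              nrow(x$scores), ncol(x$scores)))
  cat(sprintf("  embed_dim %d, %d epochs, %d parameters\n",
              x$config$embed_dim, x$config$epochs, n_parameters(x$params)))
  if (length(x$loss_trace)) {
    cat(sprintf("  loss: %.4f (first) -> %.4f (final)\n",
                x$loss_trace[1], x$loss_trace[length(x$loss_trace)]))
  }
  invisible(x)
}

#' @export
summary.hypermda <- function(object, ...) {
  s <- list(n_microbes = nrow(object$scores), n_drugs = ncol(object$scores),
            n_parameters = n_parameters(object$params),
            config = object$config,
            final_losses = object$final_losses,
            loss_trace = object$loss_trace,
            fusion_m = object$cache$fused_m[c("n_iterations", "converged")],
            fusion_d = object$cache$fused_d[c("n_iterations", "converged")])
  class(s) <- "summary.hypermda"
  s
}

#' @export
print.summary.hypermda <- function(x, ...) {
  cat(sprintf("Dual-hypergraph association model (%d x %d, %d parameters)\n",
              x$n_microbes, x$n_drugs, x$n_parameters))
  fl <- x$final_losses
  cat(sprintf("Final losses: total %.4f = reconstruction %.4f + contrastive (m) %.4f + contrastive (d) %.4f\n",
              fl$total, fl$reconstruction, fl$contrastive_m, fl$contrastive_d))
  cat(sprintf("Similarity fusion: microbes %d iter (converged %s), drugs %d iter (converged %s)\n",
              x$fusion_m$n_iterations, x$fusion_m$converged,
              x$fusion_d$n_iterations, x$fusion_d$converged))
  invisible(x)
}

#' Predict association scores
#'
#' @param object a fitted `"hypermda"` model.
#' @param pairs optional two-column matrix/data frame of (microbe, drug)
#'   pairs, as integer indices or identifier strings; `NULL` returns the
#'   full score matrix.
#' @param type `"link"` returns raw decoder scores, `"response"` maps them
#'   through a sigmoid.
#' @param ... unused.
#' @return Numeric vector of scores (or the full matrix when `pairs` is
#'   `NULL`).
#' @export
predict.hypermda <- function(object, pairs = NULL,
                             type = c("link", "response"), ...) {
  type <- match.arg(type)
  S <- object$scores
  if (type == "response") S <- 1 / (1 + exp(-S))
  if (is.null(pairs)) return(S)
  pairs <- as.matrix(pairs)
  i <- pairs[, 1]; j <- pairs[, 2]
  if (!is.numeric(i)) i <- match(i, object$microbe_ids)
  if (!is.numeric(j)) j <- match(j, object$drug_ids)
  i <- as.integer(i); j <- as.integer(j)
  if (anyNA(i) || any(i < 1 | i > nrow(S))) stop("microbe index out of range")
  if (anyNA(j) || any(j < 1 | j > ncol(S))) stop("drug index out of range")
  S[cbind(i, j)]
}

#' @export
fitted.hypermda <- function(object, ...) 1 / (1 + exp(-object$scores))

#' @export
residuals.hypermda <- function(object, ...) {
  r <- object$cache$A_train - fitted(object)
  r[object$cache$excl == 1] <- NA
  r
}

#' @export
coef.hypermda <- function(object, ...) object$params

#' Plot the training loss trace
#' @param x a fitted `"hypermda"` model.
#' @param ... passed to [plot()].
#' @export
plot.hypermda <- function(x, ...) {
  graphics::plot(seq_along(x$loss_trace), x$loss_trace, type = "l",
                 xlab = "epoch", ylab = "training loss", ...)
  invisible(x)
}

#' Simulate association matrices from the fitted probabilities
#' @param object a fitted `"hypermda"` model.
#' @param nsim number of simulated matrices.
#' @param seed optional seed.
#' @param ... unused.
#' @return List of binary matrices drawn entrywise Bernoulli from
#'   `fitted(object)`.
#' @export
simulate.hypermda <- function(object, nsim = 1, seed = NULL, ...) {
  p <- fitted(object)
  draw <- function() matrix(stats::rbinom(length(p), 1L, as.vector(p)),
                            nrow(p), ncol(p), dimnames = dimnames(p))
  if (!is.null(seed)) {
    withr::with_seed(seed, replicate(nsim, draw(), simplify = FALSE))
  } else {
    replicate(nsim, draw(), simplify = FALSE)
  }
}

#' Rank candidate entities for one target
#'
#' Orders all microbes for a given drug (or all drugs for a given microbe)
#' by decreasing predicted association score.
#'
#' @param object a fitted `"hypermda"` model.
#' @param drug,microbe exactly one of the two: an identifier or index.
#' @param n number of top candidates to return.
#' @return Data frame of candidates and scores in descending order.
#' @export
rank_candidates <- function(object, drug = NULL, microbe = NULL, n = 20L) {
  stopifnot(xor(is.null(drug), is.null(microbe)))
  S <- object$scores
  if (!is.null(drug)) {
    j <- if (is.numeric(drug)) as.integer(drug) else match(drug, object$drug_ids)
    if (is.na(j) || j < 1 || j > ncol(S)) stop("unknown drug")
    ord <- order(-S[, j], seq_len(nrow(S)))
    out <- data.frame(candidate = object$microbe_ids[ord], score = S[ord, j])
  } else {
    i <- if (is.numeric(microbe)) as.integer(microbe) else match(microbe, object$microbe_ids)
    if (is.na(i) || i < 1 || i > nrow(S)) stop("unknown microbe")
    ord <- order(-S[i, ], seq_len(ncol(S)))
    out <- data.frame(candidate = object$drug_ids[ord], score = S[i, ord])
  }
  utils::head(out, n)
}
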