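# Balanced cross-validation protocol, evaluation metrics and ablation
# switches. Confirmed pairs are the positive set; an equal-count seeded
# sample of unverified pairs forms the negative set; folds partition the
# balanced pair set with near-equal class counts per fold.

#' Build a balanced cross-validation fold plan
#'
#' All confirmed pairs are positives; the same number of unverified pairs is
#' drawn at random as negatives. Both classes are shuffled and dealt
#' round-robin into `n_folds` folds, so each fold holds near-equal numbers
#' of positives and negatives. Deterministic given `seed`.
#'
#' @param ds an [mda_dataset()].
#' @param n_folds number of folds.
#' @param seed integer seed.
#' @param n_negatives number of negatives to draw (default: one per
#'   positive); requesting more than the available unverified pairs is an
#'   error.
#' @return An object of class `"fold_plan"`: a data frame with columns
#'   `microbe`, `drug`, `label`, `fold`, plus attributes `seed` and
#'   `n_folds`.
#' @export
make_cv_folds <- function(ds, n_folds = 5L, seed = 1L, n_negatives = NULL) {
  stopifnot(inherits(ds, "mda_dataset"))
  pos <- which(ds$A == 1, arr.ind = TRUE)
  neg_pool <- which(ds$A == 0, arr.ind = TRUE)
  n_pos <- nrow(pos)
  if (n_pos < n_folds) stop("fewer positives than folds")
  if (is.null(n_negatives)) n_negatives <- n_pos
  if (n_negatives > nrow(neg_pool)) {
    stop("more negatives requested than unverified pairs available")
  }
  withr::with_seed(seed, {
    neg <- neg_pool[sample.int(nrow(neg_pool), n_negatives), , drop = FALSE]
    pos <- pos[sample.int(n_pos), , drop = FALSE]
    neg <- neg[sample.int(nrow(neg)), , drop = FALSE]
  })
  fold_of <- function(n) rep_len(seq_len(n_folds), n)
  plan <- rbind(
    data.frame(microbe = pos[, 1], drug = pos[, 2], label = 1L,
               fold = fold_of(nrow(pos))),
    data.frame(microbe = neg[, 1], drug = neg[, 2], label = 0L,
               fold = fold_of(nrow(neg))))
  rownames(plan) <- NULL
  structure(plan, class = c("fold_plan", "data.frame"),
            seed = seed, n_folds = n_folds)
}

#' Evaluate scores against binary labels
#'
#' AUC is computed as the rank (Wilcoxon-Mann-Whitney) statistic with ties
#' averaged; AUPR by step integration of the precision-recall curve in
#' descending score order; F1 and accuracy binarize the sigmoid-mapped
#' scores at `threshold`.
#'
#' @param scores numeric vector of raw (unbounded) scores.
#' @param labels binary vector of the same length; both classes must be
#'   present.
#' @param threshold classification threshold on the sigmoid scale.
#' @return List with `auc`, `aupr`, `f1`, `acc`, `threshold`.
#' @export
evaluate_scores <- function(scores, labels, threshold = 0.5) {
  stopifnot(length(scores) == length(labels))
  labels <- as.integer(labels)
  n1 <- sum(labels == 1L); n0 <- sum(labels == 0L)
  if (n1 == 0L || n0 == 0L) {
    stop("both classes must be present to compute AUC/AUPR")
  }
  r <- rank(scores, ties.method = "average")
  auc <- (sum(r[labels == 1L]) - n1 * (n1 + 1) / 2) / (n1 * n0)

  ord <- order(-scores, seq_along(scores))
  lab <- labels[ord]
  tp <- cumsum(lab)
  precision <- tp / seq_along(lab)
  recall <- tp / n1
  aupr <- sum(diff(c(0, recall)) * precision)

  prob <- 1 / (1 + exp(-scores))
  pred <- as.integer(prob >= threshold)
  tp_c <- sum(pred == 1L & labels == 1L)
  fp_c <- sum(pred == 1L & labels == 0L)
  fn_c <- sum(pred == 0L & labels == 1L)
  tn_c <- sum(pred == 0L & labels == 0L)
  prec_c <- if (tp_c + fp_c > 0) tp_c / (tp_c + fp_c) else 0
  rec_c <- if (tp_c + fn_c > 0) tp_c / (tp_c + fn_c) else 0
  f1 <- if (prec_c + rec_c > 0) 2 * prec_c * rec_c / (prec_c + rec_c) else 0
  acc <- (tp_c + tn_c) / length(labels)
  list(auc = auc, aupr = aupr, f1 = f1, acc = acc, threshold = threshold)
}

#' Run balanced k-fold cross-validation
#'
#' Trains one model per fold with the fold's pairs held out (their labels
#' hidden from the interaction-profile kernels and from both reconstruction
#' masks), scores the held-out pairs, and reports per-fold and averaged
#' metrics (mean and population standard deviation).
#'
#' @param ds an [mda_dataset()].
#' @param ms1,ds1 optional external similarity matrices.
#' @param config an [mda_config()]; `config$cv_folds` and `config$seed`
#'   drive the fold plan.
#' @param plan optional precomputed [make_cv_folds()] plan.
#' @return An object of class `"mda_cv"`: per-fold metric data frame,
#'   means, SDs, the fold plan and the config.
#' @export
run_cv <- function(ds, ms1 = NULL, ds1 = NULL, config = mda_config(),
                   plan = NULL) {
  stopifnot(inherits(ds, "mda_dataset"))
  if (is.null(plan)) plan <- make_cv_folds(ds, config$cv_folds, config$seed)
  n_folds <- attr(plan, "n_folds")
  per_fold <- vector("list", n_folds)
  for (f in seq_len(n_folds)) {
    test <- plan[plan$fold == f, ]
    log_msg(config, "fold %d/%d: %d test pairs", f, n_folds, nrow(test))
    fit <- hypermda(ds, ms1, ds1, config,
                    exclude = as.matrix(test[, c("microbe", "drug")]))
    sc <- predict(fit, test[, c("microbe", "drug")])
    m <- evaluate_scores(sc, test$label, config$threshold)
    per_fold[[f]] <- data.frame(fold = f, auc = m$auc, aupr = m$aupr,
                                f1 = m$f1, acc = m$acc)
  }
  metrics <- do.call(rbind, per_fold)
  pop_sd <- function(x) sqrt(mean((x - mean(x))^2))
  means <- colMeans(metrics[, -1])
  sds <- vapply(metrics[, -1], pop_sd, numeric(1))
  structure(list(metrics = metrics, means = means, sds = sds,
                 plan = plan, config = config),
            class = "mda_cv")
}

#' @export
print.mda_cv <- function(x, ...) {
  cat(sprintf("%d-fold balanced cross-validation (seed %d)\n",
              attr(x$plan, "n_folds"), attr(x$plan, "seed")))
  print(x$metrics, row.names = FALSE, digits = 4)
  for (m in names(x$means)) {
    cat(sprintf("  mean %s = %.4f +/- %.4f\n", m, x$means[[m]], x$sds[[m]]))
  }
  invisible(x)
}

#' Derive an ablation configuration
#'
#' * `NoDHA`: replaces hierarchical attention by a direct feature
#'   projection into the convolution stack.
#' * `NoCL`: drops the contrastive terms (`lambda_m = gamma_d = 0`, the
#'   contrastive computation is skipped).
#' * `MS1DS1`: only the external similarity matrices are used.
#' * `MS2DS2`: only the interaction-profile kernels are used.
#' * `Linear`: element-wise average fusion instead of non-linear fusion.
#'
#' @param config an [mda_config()].
#' @param variant one of `"NoDHA"`, `"NoCL"`, `"MS1DS1"`, `"MS2DS2"`,
#'   `"Linear"`.
#' @return The modified `"mda_config"`.
#' @export
ablate <- function(config, variant = c("NoDHA", "NoCL", "MS1DS1", "MS2DS2",
                                       "Linear")) {
  variant <- match.arg(variant)
  stopifnot(inherits(config, "mda_config"))
  switch(variant,
    NoDHA = { config$use_dha <- FALSE },
    NoCL = {
      config$use_cl <- FALSE
      config$lambda_m <- 0
      config$gamma_d <- 0
    },
    MS1DS1 = { config$similarity_views <- "external" },
    MS2DS2 = { config$similarity_views <- "gip" },
    Linear = { config$fusion <- "linear" })
  config
}

#' Write a cross-validation report as JSON
#'
#' @param cv an `"mda_cv"` object.
#' @param path output path.
#' @export
write_cv_report <- function(cv, path) {
  rep <- list(per_fold = cv$metrics,
              mean = as.list(cv$means), sd = as.list(cv$sds),
              threshold = cv$config$threshold, seed = cv$config$seed)
  jsonlite::write_json(rep, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "columns")
  invisible(path)
}
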