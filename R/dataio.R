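# Association-matrix and similarity-matrix I/O, dataset summaries, run
# configuration.
#
# On-disk conventions:
#   * dense TSV: first cell empty, then drug ids; each following row is a
#     microbe id followed by 0/1 values.
#   * edge list TSV: microbe_id <TAB> drug_id <TAB> value, absent pairs are 0.
# Row/column labels are always identifier strings, never positions; matrices
# are oriented microbes x drugs (rows = microbes).

#' Construct a microbe-drug association dataset
#'
#' Bundles a binary association matrix with its microbe and drug identifier
#' lists and validates the invariants (binary entries, unique non-empty
#' identifier lists, matching dimensions).
#'
#' @param A binary numeric matrix, rows = microbes, columns = drugs; entry 1
#'   marks an experimentally confirmed association.
#' @param microbe_ids,drug_ids character vectors of unique identifiers; taken
#'   from `dimnames(A)` when omitted.
#' @return An object of class `"mda_dataset"`: a list with elements
#'   `microbe_ids`, `drug_ids` and `A`.
#' @examples
#' ds <- mda_dataset(matrix(c(1, 0, 0, 1), 2, 2))
#' dataset_summary(ds)
#' @export
mda_dataset <- function(A, microbe_ids = NULL, drug_ids = NULL) {
  A <- as.matrix(A)
  if (is.null(microbe_ids)) {
    microbe_ids <- rownames(A)
    if (is.null(microbe_ids)) microbe_ids <- paste0("m", seq_len(nrow(A)))
  }
  if (is.null(drug_ids)) {
    drug_ids <- colnames(A)
    if (is.null(drug_ids)) drug_ids <- paste0("d", seq_len(ncol(A)))
  }
  if (nrow(A) == 0L || ncol(A) == 0L) {
    stop("association matrix must have at least one microbe and one drug")
  }
  if (length(microbe_ids) != nrow(A) || length(drug_ids) != ncol(A)) {
    stop("identifier lists do not match the matrix dimensions")
  }
  if (anyDuplicated(microbe_ids)) stop("duplicate microbe identifiers")
  if (anyDuplicated(drug_ids)) stop("duplicate drug identifiers")
  if (anyNA(A) || !all(A %in% c(0, 1))) {
    stop("association matrix entries must all be 0 or 1")
  }
  storage.mode(A) <- "double"
  dimnames(A) <- list(microbe_ids, drug_ids)
  structure(list(microbe_ids = as.character(microbe_ids),
                 drug_ids = as.character(drug_ids),
                 A = A),
            class = "mda_dataset")
}

#' @export
print.mda_dataset <- function(x, ...) {
  s <- dataset_summary(x)
  cat(sprintf("Microbe-drug association dataset: %d microbes x %d drugs, %d associations (density %.2f%%)\n",
              s$n_microbes, s$n_drugs, s$n_associations, s$density_percent))
  invisible(x)
}

#' Read an association matrix from disk
#'
#' @param path path to a TSV file.
#' @param format `"dense"` (header of drug ids, one row per microbe),
#'   `"edgelist"` (three columns: microbe id, drug id, value) or `"auto"`
#'   (edge list if the file has exactly 3 columns and no leading empty cell).
#' @param microbe_ids,drug_ids for the edge-list format, the declared
#'   identifier universe; defaults to the identifiers present in the file.
#' @return An [mda_dataset()].
#' @export
read_association <- function(path, format = c("auto", "dense", "edgelist"),
                             microbe_ids = NULL, drug_ids = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "auto") {
    first <- strsplit(readLines(path, n = 1L), "\t", fixed = TRUE)[[1]]
    format <- if (length(first) == 3L && !identical(first[1], "")) "edgelist" else "dense"
  }
  if (format == "dense") {
    tab <- utils::read.table(path, sep = "\t", header = TRUE, row.names = 1L,
                             check.names = FALSE, colClasses = NA)
    A <- as.matrix(tab)
    if (!is.numeric(A)) stop("parse error: non-numeric entries in dense association table")
    bad <- which(!(A %in% c(0, 1)))
    if (length(bad)) {
      stop(sprintf("non-binary value %s at row %d of the dense table",
                   format(A[bad[1]]), ((bad[1] - 1L) %% nrow(A)) + 1L))
    }
    mda_dataset(A, rownames(A), colnames(A))
  } else {
    tab <- utils::read.table(path, sep = "\t", header = FALSE,
                             col.names = c("microbe_id", "drug_id", "value"),
                             colClasses = c("character", "character", "numeric"))
    if (anyNA(tab$value)) {
      stop("parse error: malformed value on line ", which(is.na(tab$value))[1])
    }
    if (!all(tab$value %in% c(0, 1))) {
      stop("non-binary value on line ", which(!(tab$value %in% c(0, 1)))[1])
    }
    key <- paste(tab$microbe_id, tab$drug_id, sep = "\r")
    if (anyDuplicated(key)) {
      dup <- key[duplicated(key)]
      conf <- tapply(tab$value, key, function(v) length(unique(v)) > 1L)
      if (any(conf)) stop("duplicate edge with conflicting value: ",
                          sub("\r", " / ", names(conf)[conf][1]))
      tab <- tab[!duplicated(key), ]
    }
    if (is.null(microbe_ids)) microbe_ids <- sort(unique(tab$microbe_id))
    if (is.null(drug_ids)) drug_ids <- sort(unique(tab$drug_id))
    miss_m <- setdiff(tab$microbe_id, microbe_ids)
    miss_d <- setdiff(tab$drug_id, drug_ids)
    if (length(miss_m) || length(miss_d)) {
      stop("edge list mentions undeclared identifiers: ",
           paste(c(miss_m, miss_d), collapse = ", "))
    }
    A <- matrix(0, length(microbe_ids), length(drug_ids),
                dimnames = list(microbe_ids, drug_ids))
    A[cbind(match(tab$microbe_id, microbe_ids),
            match(tab$drug_id, drug_ids))] <- tab$value
    mda_dataset(A, microbe_ids, drug_ids)
  }
}

#' Write an association dataset to disk
#'
#' @param ds an [mda_dataset()].
#' @param path output path.
#' @param format `"dense"` or `"edgelist"` (only nonzero pairs are written).
#' @export
write_association <- function(ds, path, format = c("dense", "edgelist")) {
  format <- match.arg(format)
  stopifnot(inherits(ds, "mda_dataset"))
  if (format == "dense") {
    header <- paste(c("", ds$drug_ids), collapse = "\t")
    rows <- vapply(seq_along(ds$microbe_ids), function(i) {
      paste(c(ds$microbe_ids[i], format(ds$A[i, ], trim = TRUE)), collapse = "\t")
    }, character(1))
    writeLines(c(header, rows), path)
  } else {
    idx <- which(ds$A != 0, arr.ind = TRUE)
    lines <- sprintf("%s\t%s\t%g", ds$microbe_ids[idx[, 1]],
                     ds$drug_ids[idx[, 2]], ds$A[idx])
    writeLines(lines, path)
  }
  invisible(path)
}

#' Summarize an association dataset
#'
#' Density is the percentage of observed pairs among all microbe-drug pairs,
#' reported to two decimals.
#'
#' @param ds an [mda_dataset()].
#' @return A list with `n_microbes`, `n_drugs`, `n_associations` and
#'   `density_percent`.
#' @export
dataset_summary <- function(ds) {
  stopifnot(inherits(ds, "mda_dataset"))
  n_assoc <- sum(ds$A != 0)
  nm <- nrow(ds$A); nd <- ncol(ds$A)
  list(n_microbes = nm,
       n_drugs = nd,
       n_associations = n_assoc,
       density_percent = round(100 * n_assoc / (nm * nd), 2))
}

#' Read a similarity matrix from disk
#'
#' Reads a labelled square TSV matrix, reindexes it to the given identifier
#' order, validates that values lie in \[0, 1\] and symmetrizes as
#' `(S + t(S)) / 2` (with a warning) when asymmetry exceeds 1e-8. Identifiers
#' absent from the file are an error; missing pairwise entries in the file
#' (NA) are read as 0 — sparse external similarities are expected and are
#' handled downstream by fusion, not by imputation.
#'
#' @param path path to a TSV with row and column labels.
#' @param entity_ids ordered identifiers the matrix must be indexed by.
#' @return A square numeric matrix in `entity_ids` order.
#' @export
read_similarity <- function(path, entity_ids) {
  if (!file.exists(path)) stop("file not found: ", path)
  tab <- utils::read.table(path, sep = "\t", header = TRUE, row.names = 1L,
                           check.names = FALSE)
  S <- as.matrix(tab)
  miss <- union(setdiff(entity_ids, rownames(S)), setdiff(entity_ids, colnames(S)))
  if (length(miss)) {
    stop("similarity matrix is missing identifiers: ", paste(miss, collapse = ", "))
  }
  S <- S[entity_ids, entity_ids, drop = FALSE]
  S[is.na(S)] <- 0
  validate_similarity(S)
}

#' Validate (and if needed symmetrize) a similarity matrix
#' @param S square numeric matrix with values in \[0, 1\].
#' @return The validated, symmetric matrix.
#' @export
validate_similarity <- function(S) {
  S <- as.matrix(S)
  if (nrow(S) != ncol(S)) stop("similarity matrix must be square")
  if (anyNA(S) || min(S) < 0 || max(S) > 1) {
    stop("similarity values must lie in [0, 1]")
  }
  if (max(abs(S - t(S))) > 1e-8) {
    warning("asymmetric similarity matrix; symmetrizing as (S + t(S))/2")
    S <- (S + t(S)) / 2
  }
  S
}

#' Write a similarity matrix to disk
#' @param S square labelled matrix.
#' @param path output path.
#' @export
write_similarity <- function(S, path) {
  ids <- rownames(S)
  if (is.null(ids)) ids <- paste0("e", seq_len(nrow(S)))
  header <- paste(c("", ids), collapse = "\t")
  rows <- vapply(seq_len(nrow(S)), function(i) {
    paste(c(ids[i], format(S[i, ], trim = TRUE, digits = 15)), collapse = "\t")
  }, character(1))
  writeLines(c(header, rows), path)
  invisible(path)
}

#' Run configuration
#'
#' Collects all tunable parameters of the model and training loop with the
#' reference defaults: embedding dimension 256, 400 epochs of Adam at
#' learning rate 1e-4, reconstruction trade-off `alpha = 0.11`, contrastive
#' weights `lambda_m = gamma_d = 1`, temperature `tau = 0.5`, 5 attention
#' heads, 2 hypergraph-convolution layers, `knn_k = 13` neighbours and
#' `ko_c = 9` cluster centres for the two hypergraph views, and balanced
#' 5-fold cross-validation.
#'
#' @param embed_dim embedding dimension d.
#' @param epochs training epochs.
#' @param learning_rate Adam learning rate.
#' @param alpha trade-off in \[0,1\] between observed and unobserved entries
#'   of the reconstruction loss (weight `(1-alpha)/2` on observed,
#'   `alpha/2` on unobserved).
#' @param lambda_m,gamma_d weights of the microbe and drug contrastive losses.
#' @param tau InfoNCE temperature (> 0).
#' @param n_heads number of inter-view attention heads.
#' @param hgcn_layers number of hypergraph convolution layers.
#' @param knn_k neighbours per hyperedge in the KNN view.
#' @param ko_c cluster count in the clustering (KO) view.
#' @param cv_folds number of cross-validation folds.
#' @param seed integer seed governing all randomness.
#' @param threshold score threshold (after sigmoid) for F1/accuracy.
#' @param attention_norm `"softmax"` (default) or `"ratio"`: how raw
#'   scaled-dot attention scores are normalized at both hierarchy levels.
#' @param include_centroid whether each KNN hyperedge contains its own
#'   centroid node in addition to its k neighbours.
#' @param fusion `"snf"` (iterative non-linear fusion) or `"linear"`.
#' @param snf_k neighbour count of the fusion's local kernel; default
#'   `max(1, floor(N/10))`.
#' @param snf_tol,snf_max_iter fusion convergence tolerance / iteration cap.
#' @param ko_pop_size,ko_max_iter population size and iteration cap of the
#'   clustering optimizer.
#' @param use_dha `FALSE` replaces hierarchical attention with a direct
#'   feature projection into the convolution stack (ablation).
#' @param use_cl `FALSE` drops the contrastive terms (ablation).
#' @param similarity_views `"both"`, `"external"` (only the supplied
#'   functional/structural matrices) or `"gip"` (only the interaction-profile
#'   kernels).
#' @param verbose logical; print a config echo and progress.
#' @return An object of class `"mda_config"` (a named list).
#' @export
mda_config <- function(embed_dim = 256L, epochs = 400L, learning_rate = 1e-4,
                       alpha = 0.11, lambda_m = 1, gamma_d = 1, tau = 0.5,
                       n_heads = 5L, hgcn_layers = 2L, knn_k = 13L, ko_c = 9L,
                       cv_folds = 5L, seed = 1L, threshold = 0.5,
                       attention_norm = c("softmax", "ratio"),
                       include_centroid = TRUE,
                       fusion = c("snf", "linear"),
                       snf_k = NULL, snf_tol = 1e-5, snf_max_iter = 50L,
                       ko_pop_size = 10L, ko_max_iter = 100L,
                       use_dha = TRUE, use_cl = TRUE,
                       similarity_views = c("both", "external", "gip"),
                       verbose = FALSE) {
  cfg <- list(embed_dim = as.integer(embed_dim), epochs = as.integer(epochs),
              learning_rate = learning_rate, alpha = alpha,
              lambda_m = lambda_m, gamma_d = gamma_d, tau = tau,
              n_heads = as.integer(n_heads), hgcn_layers = as.integer(hgcn_layers),
              knn_k = as.integer(knn_k), ko_c = as.integer(ko_c),
              cv_folds = as.integer(cv_folds), seed = as.integer(seed),
              threshold = threshold,
              attention_norm = match.arg(attention_norm),
              include_centroid = isTRUE(include_centroid),
              fusion = match.arg(fusion),
              snf_k = if (is.null(snf_k)) NULL else as.integer(snf_k),
              snf_tol = snf_tol, snf_max_iter = as.integer(snf_max_iter),
              ko_pop_size = as.integer(ko_pop_size),
              ko_max_iter = as.integer(ko_max_iter),
              use_dha = isTRUE(use_dha), use_cl = isTRUE(use_cl),
              similarity_views = match.arg(similarity_views),
              verbose = isTRUE(verbose))
  stopifnot(cfg$embed_dim > 0, cfg$epochs >= 0, cfg$learning_rate > 0,
            cfg$alpha >= 0, cfg$alpha <= 1, cfg$tau > 0, cfg$n_heads > 0,
            cfg$hgcn_layers >= 1, cfg$knn_k >= 1, cfg$ko_c >= 2,
            cfg$cv_folds >= 2, cfg$threshold > 0, cfg$threshold < 1)
  if (cfg$n_heads > cfg$embed_dim) {
    stop("n_heads cannot exceed embed_dim")
  }
  structure(cfg, class = "mda_config")
}

#' Read a run configuration from a flat YAML file
#'
#' Fields mirror the arguments of [mda_config()]; unknown fields are an
#' error. Values given in `...` override the file.
#'
#' @param path YAML file path.
#' @param ... overrides applied after reading the file.
#' @return An `"mda_config"` object.
#' @export
read_config <- function(path, ...) {
  vals <- yaml::read_yaml(path)
  over <- list(...)
  vals[names(over)] <- over
  unknown <- setdiff(names(vals), names(formals(mda_config)))
  if (length(unknown)) stop("unknown config fields: ", paste(unknown, collapse = ", "))
  do.call(mda_config, vals)
}

#' @export
print.mda_config <- function(x, ...) {
  cat("Run configuration:\n")
  for (nm in names(x)) {
    v <- x[[nm]]
    cat(sprintf("  %-16s %s\n", nm, if (is.null(v)) "<auto>" else format(v)))
  }
  invisible(x)
}

# Lightweight logging helper; honours cfg$verbose.
log_msg <- function(cfg, ...) {
  if (!is.null(cfg) && isTRUE(cfg$verbose)) message(sprintf(...))
  invisible(NULL)
}
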