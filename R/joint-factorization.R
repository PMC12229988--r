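.block_scores <- function(x) {
  if (inherits(x, "filtered_block")) return(x$pca$scores)
  if (inherits(x, "pca_model")) return(x$scores)
  as.matrix(x)
}

.check_shared_samples <- function(score_list) {
  ref <- rownames(score_list[[1]])
  if (is.null(ref)) stop("blocks must carry sample identifiers as rownames")
  for (i in seq_along(score_list)) {
    ids <- rownames(score_list[[i]])
    missing <- union(setdiff(ref, ids), setdiff(ids, ref))
    if (length(missing) > 0) {
      stop("blocks do not share the same samples; offending samples: ",
           paste(utils::head(missing, 5), collapse = ", "))
    }
  }
  ref
}

#' Fit a joint factorization across PCA-filtered blocks
#'
#' Default backend `"mfa_svd"`: a deterministic multiple-factor-analysis
#' style joint SVD. Each block's score matrix is divided by its own first
#' singular value (so no block dominates by scale), the scaled blocks are
#' concatenated along features, and the top-K left singular vectors of the
#' concatenation become the factor scores; per-block weights are the
#' corresponding slices of the right singular vectors scaled back to each
#' block's own units, so that `scores %*% t(block_weights[[m]])`
#' approximates block m's (PC-score) matrix. Each factor's sign is fixed by
#' making the largest-magnitude entry of its concatenated weight vector
#' positive.
#'
#' An external stochastic backend can be plugged in by passing a function
#' `method(score_list, K, seed)` returning `list(scores =, block_weights =)`
#' of the same shapes.
#'
#' @param blocks Named list of `filtered_block` objects (or plain
#'   samples x variables matrices with sample rownames).
#' @param K Number of factors (default 5).
#' @param method `"mfa_svd"` or a backend function (see Details).
#' @param seed Seed recorded in the model and passed to stochastic
#'   backends (the default backend is deterministic).
#' @return An object of class `factor_model` with `scores` (samples x K),
#'   `block_weights` (per block: k_m x K), `variance_explained`
#'   (blocks x K) and metadata.
#' @export
fit_jdr <- function(blocks, K = 5, method = "mfa_svd", seed = 13) {
  K <- .check_count(K, "K", min = 1)
  if (is.null(names(blocks))) names(blocks) <- paste0("block", seq_along(blocks))
  s_list <- lapply(blocks, .block_scores)
  ids <- .check_shared_samples(s_list)
  s_list <- lapply(s_list, function(s) s[ids, , drop = FALSE])

  if (is.function(method)) {
    fit <- method(s_list, K, seed)
    z <- fit$scores
    a_list <- fit$block_weights
    method_label <- attr(method, "label") %||% "external"
  } else if (identical(method, "mfa_svd")) {
    s1 <- vapply(s_list, function(s) svd(s, nu = 0, nv = 0)$d[1], numeric(1))
    s1[s1 == 0] <- 1
    x <- do.call(cbind, Map(function(s, d) s / d, s_list, as.list(s1)))
    if (K > min(dim(x))) {
      stop(sprintf("K = %d exceeds the available rank (%d)", K, min(dim(x))))
    }
    sv <- svd(x)
    rank <- sum(sv$d > max(dim(x)) * .Machine$double.eps * sv$d[1])
    if (K > rank) {
      stop(sprintf("K = %d exceeds the available rank (%d)", K, rank))
    }
    z <- sv$u[, seq_len(K), drop = FALSE]
    offsets <- c(0, cumsum(vapply(s_list, ncol, integer(1))))
    a_list <- vector("list", length(s_list))
    names(a_list) <- names(blocks)
    for (m in seq_along(s_list)) {
      idx <- (offsets[m] + 1):offsets[m + 1]
      a <- s1[m] * sv$v[idx, seq_len(K), drop = FALSE] %*%
        diag(sv$d[seq_len(K)], K, K)
      rownames(a) <- colnames(s_list[[m]])
      a_list[[m]] <- a
    }
    method_label <- "mfa_svd"
  } else {
    stop("unknown factorization method: ", method)
  }

  rownames(z) <- ids
  colnames(z) <- paste0("Factor", seq_len(K))
  for (k in seq_len(K)) {
    w <- unlist(lapply(a_list, function(a) a[, k]))
    if (w[which.max(abs(w))] < 0) {
      z[, k] <- -z[, k]
      for (m in seq_along(a_list)) a_list[[m]][, k] <- -a_list[[m]][, k]
    }
  }
  for (m in seq_along(a_list)) colnames(a_list[[m]]) <- colnames(z)

  model <- structure(list(scores = z, block_weights = a_list,
                          variance_explained = NULL, method = method_label,
                          K = K, seed = seed),
                     class = "factor_model")
  model$variance_explained <- variance_explained(model, blocks)
  model
}

#' @export
print.factor_model <- function(x, ...) {
  cat(sprintf("<factor_model> %d factors x %d samples (%s), %d block(s)\n",
              x$K, nrow(x$scores), x$method, length(x$block_weights)))
  invisible(x)
}

.model_scores <- function(model) {
  if (inherits(model, "factor_model")) model$scores else as.matrix(model)
}

#' Per-block, per-factor variance explained
#'
#' For block m and factor k, `R2 = 1 - |S_m - z_k a_mk'|^2_F / |S_m|^2_F`
#' on the column-centered block score matrices, i.e. the fraction of the
#' block's variance captured by that factor alone.
#'
#' @param model A `factor_model`.
#' @param blocks The blocks the model was fitted on.
#' @return A blocks x K matrix of variance fractions.
#' @export
variance_explained <- function(model, blocks) {
  if (is.null(names(blocks))) names(blocks) <- names(model$block_weights)
  K <- model$K
  out <- matrix(NA_real_, length(blocks), K,
                dimnames = list(names(blocks), colnames(model$scores)))
  z <- model$scores[, , drop = FALSE]
  for (m in seq_along(blocks)) {
    s <- .block_scores(blocks[[m]])[rownames(z), , drop = FALSE]
    a <- model$block_weights[[m]]
    if (nrow(a) != ncol(s)) {
      stop(sprintf("block '%s' has %d variables but the model carries %d weights",
                   names(blocks)[m], ncol(s), nrow(a)))
    }
    s <- sweep(s, 2, colMeans(s))
    total <- sum(s^2)
    for (k in seq_len(K)) {
      res <- s - z[, k, drop = FALSE] %*% t(a[, k, drop = FALSE])
      out[m, k] <- 1 - sum(res^2) / total
    }
  }
  out
}

#' Back-map factor weights from PC space to original features
#'
#' Multiplies the PCA loadings (features x PCs) by the factor weights
#' (PCs x factors) to obtain per-feature factor weights. With all PCs
#' retained and a linear factorization backend this reconstruction is
#' exactly the weight matrix a direct fit on the original features would
#' give (up to per-factor sign); with truncated PCs it is an approximation
#' whose feature rankings — the quantity used downstream — are stable.
#' No normalization is applied.
#'
#' @param pca_loadings Features x k_m loading matrix.
#' @param block_weights k_m x K factor-weight matrix.
#' @return A features x K weight matrix.
#' @export
backmap_weights <- function(pca_loadings, block_weights) {
  pca_loadings <- as.matrix(pca_loadings)
  block_weights <- as.matrix(block_weights)
  if (ncol(pca_loadings) != nrow(block_weights)) {
    stop(sprintf("inner dimensions disagree: %d loadings columns vs %d weight rows",
                 ncol(pca_loadings), nrow(block_weights)))
  }
  pca_loadings %*% block_weights
}

#' Back-map every block of a fitted model
#'
#' @param model A `factor_model` fitted on `blocks`.
#' @param blocks Named list of `filtered_block` objects.
#' @return Named list of features x K weight matrices.
#' @export
backmap_model <- function(model, blocks) {
  out <- list()
  for (nm in names(blocks)) {
    if (!inherits(blocks[[nm]], "filtered_block")) next
    out[[nm]] <- backmap_weights(blocks[[nm]]$pca$loadings,
                                 model$block_weights[[nm]])
  }
  out
}

#' Absolute correlation between the factors of two models
#'
#' Pairwise absolute Pearson correlation between factor-score columns on
#' the samples shared by both models; used to match factors between model
#' variants (e.g. with and without network blocks).
#'
#' @param model_a,model_b `factor_model` objects (or score matrices).
#' @return A K_A x K_B matrix with entries in [0, 1].
#' @export
factor_correlation <- function(model_a, model_b) {
  za <- .model_scores(model_a)
  zb <- .model_scores(model_b)
  shared <- intersect(rownames(za), rownames(zb))
  if (length(shared) < 3) stop("fewer than 3 shared samples between the models")
  abs(stats::cor(za[shared, , drop = FALSE], zb[shared, , drop = FALSE]))
}

#' Serialize a factor model
#'
#' Writes factor scores and per-block weights as TSV plus YAML metadata.
#'
#' @param model A `factor_model`.
#' @param dir Output directory.
#' @return The metadata path, invisibly.
#' @export
write_factor_model <- function(model, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  .write_matrix_tsv(model$scores, file.path(dir, "factor_scores.tsv"),
                    id_col = "sample_id")
  for (nm in names(model$block_weights)) {
    .write_matrix_tsv(model$block_weights[[nm]],
                      file.path(dir, paste0("weights_", nm, ".tsv")),
                      id_col = "pc")
  }
  meta <- file.path(dir, "model.yaml")
  yaml::write_yaml(list(method = model$method, K = model$K, seed = model$seed),
                   meta)
  invisible(meta)
}
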