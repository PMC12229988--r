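#' Remove zero-variance features from an omics block
#'
#' Features that are constant across samples carry no signal and break
#' unit-variance scaling, so they are dropped before PCA.
#'
#' @param block An `omics_block`.
#' @return The filtered `omics_block`; the identifiers of removed features
#'   are attached as attribute `"dropped_features"`.
#' @export
drop_zero_variance <- function(block) {
  x <- .block_values(block)
  keep <- .row_sds(x) > 0
  if (!any(keep)) stop("all features have zero variance")
  dropped <- rownames(x)[!keep]
  if (length(dropped) > 0) {
    message(sprintf("dropping %d zero-variance feature(s) from '%s' (%d kept)",
                    length(dropped), block$name, sum(keep)))
  }
  out <- omics_block(x[keep, , drop = FALSE], name = block$name)
  attr(out, "dropped_features") <- dropped
  out
}

#' Fit a principal component analysis on an omics block
#'
#' Samples are observations and features variables; the decomposition is
#' computed by singular value decomposition of the (optionally centered and
#' unit-variance scaled) data. Each component is oriented so that its
#' largest-magnitude loading entry is positive, removing the SVD sign
#' ambiguity.
#'
#' @param block An `omics_block` (features x samples).
#' @param center,scale Center each feature / scale to unit variance.
#' @return An object of class `pca_model` with `scores` (samples x k),
#'   `loadings` (features x k, orthonormal columns), `variance_ratios`
#'   (non-increasing, summing to <= 1) and the centering/scaling vectors.
#' @export
fit_pca <- function(block, center = TRUE, scale = TRUE) {
  x <- t(.block_values(block))
  if (nrow(x) < 2 || ncol(x) < 2) {
    stop("PCA requires at least 2 samples and 2 features")
  }
  if (scale && any(apply(x, 2, stats::sd) == 0)) {
    stop("zero-variance features present; apply drop_zero_variance() first")
  }
  pr <- stats::prcomp(x, center = center, scale. = scale)
  for (j in seq_len(ncol(pr$rotation))) {
    i <- which.max(abs(pr$rotation[, j]))
    if (pr$rotation[i, j] < 0) {
      pr$rotation[, j] <- -pr$rotation[, j]
      pr$x[, j] <- -pr$x[, j]
    }
  }
  vr <- pr$sdev^2 / sum(pr$sdev^2)
  structure(list(
    scores = pr$x,
    loadings = pr$rotation,
    variance_ratios = vr,
    center = if (isTRUE(center)) pr$center else NULL,
    scale = if (isTRUE(scale)) pr$scale else NULL,
    feature_ids = colnames(x),
    sample_ids = rownames(x)
  ), class = "pca_model")
}

#' Number of principal components reaching a cumulative variance threshold
#'
#' Returns `max(floor, smallest j with cumulative variance >= threshold)`,
#' capped at the number of available components. The floor guards against
#' omics whose variance concentrates in very few components, which would
#' otherwise enter the joint factorization with dimensionality orders of
#' magnitude below the other blocks.
#'
#' @param variance_ratios Non-negative, non-increasing variance fractions.
#' @param threshold Cumulative variance target (default 0.85).
#' @param floor Minimum number of components (default 20).
#' @return The selected number of components (integer).
#' @export
select_num_pcs <- function(variance_ratios, threshold = 0.85, floor = 20) {
  if (length(variance_ratios) == 0) stop("empty variance-ratio vector")
  if (any(variance_ratios < -1e-12)) stop("variance ratios must be non-negative")
  if (any(diff(variance_ratios) > 1e-8)) {
    stop("variance ratios must be non-increasing")
  }
  threshold <- .check_fraction(threshold, "threshold")
  floor <- .check_count(floor, "floor", min = 1)
  cum <- cumsum(variance_ratios)
  j <- which(cum >= threshold - 1e-9)
  j <- if (length(j) == 0) length(variance_ratios) else j[1]
  as.integer(min(length(variance_ratios), max(floor, j)))
}

#' PCA-filter an omics block
#'
#' Composes the zero-variance filter, PCA, and component selection: the
#' block is reduced to the smallest number of principal components whose
#' cumulative variance reaches `threshold`, subject to a floor (capped at
#' the available rank, with a warning when the floor exceeds it).
#'
#' @inheritParams fit_pca
#' @inheritParams select_num_pcs
#' @return An object of class `filtered_block` with the source `name`, the
#'   truncated `pca` model, `k_selected` and `retained_variance`.
#' @export
filter_block <- function(block, threshold = 0.85, floor = 20,
                         center = TRUE, scale = TRUE) {
  block <- drop_zero_variance(block)
  pca <- fit_pca(block, center = center, scale = scale)
  avail <- length(pca$variance_ratios)
  if (floor > avail) {
    warning(sprintf("floor (%d) exceeds the available rank of '%s' (%d); capping",
                    floor, block$name, avail))
  }
  k <- select_num_pcs(pca$variance_ratios, threshold = threshold, floor = floor)
  retained <- sum(pca$variance_ratios[seq_len(k)])
  pca$scores <- pca$scores[, seq_len(k), drop = FALSE]
  pca$loadings <- pca$loadings[, seq_len(k), drop = FALSE]
  pca$variance_ratios <- pca$variance_ratios[seq_len(k)]
  structure(list(name = block$name, pca = pca, k_selected = k,
                 retained_variance = retained, threshold = threshold),
            class = "filtered_block")
}

#' @export
print.filtered_block <- function(x, ...) {
  cat(sprintf("<filtered_block> '%s': %d PCs retained (%.1f%% variance)\n",
              x$name, x$k_selected, 100 * x$retained_variance))
  invisible(x)
}

#' Serialize a filtered block
#'
#' Writes scores and loadings as TSV plus a YAML sidecar recording the
#' threshold, selection and centering/scaling vectors.
#'
#' @param fb A `filtered_block`.
#' @param dir Output directory.
#' @return The sidecar path, invisibly.
#' @export
write_filtered_block <- function(fb, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  scores_path <- file.path(dir, paste0(fb$name, "_scores.tsv"))
  loadings_path <- file.path(dir, paste0(fb$name, "_loadings.tsv"))
  .write_matrix_tsv(fb$pca$scores, scores_path, id_col = "sample_id")
  .write_matrix_tsv(fb$pca$loadings, loadings_path, id_col = "feature_id")
  sidecar <- file.path(dir, paste0(fb$name, "_pca.yaml"))
  yaml::write_yaml(list(
    name = fb$name, threshold = fb$threshold, k_selected = fb$k_selected,
    retained_variance = fb$retained_variance,
    center = as.list(fb$pca$center), scale = as.list(fb$pca$scale)
  ), sidecar)
  invisible(sidecar)
}
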