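#' Construct a set of single-sample networks
#'
#' Houses per-sample edge weights over a common TF x gene edge universe.
#' Edge weights are stored sample-by-edge, edges in column-major order of
#' the TF x gene matrix (TF index varying fastest).
#'
#' @param weights Samples x (n_tfs * n_genes) numeric matrix.
#' @param tf_ids,gene_ids Node identifiers.
#' @param sample_ids Sample identifiers (default: rownames or generated).
#' @return An object of class `sample_network_set`.
#' @export
sample_network_set <- function(weights, tf_ids, gene_ids, sample_ids = NULL) {
  weights <- as.matrix(weights)
  if (nrow(weights) < 2) stop("a sample network set requires at least 2 samples")
  if (ncol(weights) != length(tf_ids) * length(gene_ids)) {
    stop("edge count does not match length(tf_ids) * length(gene_ids)")
  }
  sample_ids <- sample_ids %||% rownames(weights) %||% .make_ids("S", nrow(weights))
  rownames(weights) <- sample_ids
  structure(list(weights = weights, tf_ids = tf_ids, gene_ids = gene_ids,
                 sample_ids = sample_ids),
            class = "sample_network_set")
}

#' @export
print.sample_network_set <- function(x, ...) {
  cat(sprintf("<sample_network_set> %d samples, %d TFs x %d genes\n",
              nrow(x$weights), length(x$tf_ids), length(x$gene_ids)))
  invisible(x)
}

#' Gene-gene co-expression matrix
#'
#' Pairwise Pearson correlation of gene rows across samples; the diagonal is
#' set to exactly 1.
#'
#' @param expr An `omics_block` (genes x samples) or numeric matrix.
#' @return A gene x gene correlation matrix of class `coexpression`.
#' @export
compute_coexpression <- function(expr) {
  x <- .block_values(expr)
  if (ncol(x) < 3) stop("co-expression requires at least 3 samples")
  sds <- .row_sds(x)
  if (any(sds == 0)) {
    bad <- rownames(x)[sds == 0]
    stop("zero-variance gene(s): ", paste(utils::head(bad, 5), collapse = ", "),
         if (length(bad) > 5) sprintf(" (and %d more)", length(bad) - 5) else "")
  }
  co <- stats::cor(t(x))
  diag(co) <- 1
  class(co) <- c("coexpression", class(co))
  co
}

# overall z-score normalization used on the three network-inference inputs
.znorm <- function(m) {
  s <- stats::sd(m)
  if (!is.finite(s) || s == 0) return(m - mean(m))
  (m - mean(m)) / s
}

# continuous Tanimoto similarity T(x, y) = <x,y> / sqrt(|x|^2 + |y|^2 - |<x,y>|),
# assembled from a precomputed inner-product matrix and squared norms
.tanimoto <- function(num, xsq, ysq) {
  den <- outer(xsq, ysq, "+") - abs(num)
  den[den < .Machine$double.eps] <- .Machine$double.eps
  num / sqrt(den)
}

#' Message-passing aggregate network inference
#'
#' Infers a complete bipartite TF x gene network by iteratively finding
#' agreement between a motif prior, a TF-TF interaction prior, and gene
#' co-expression. All three inputs are z-score normalized; at each
#' iteration, a responsibility matrix (TF-TF prior vs. network columns) and
#' an availability matrix (network rows vs. co-expression) are computed
#' with a continuous Tanimoto similarity, and the network is moved a step
#' `alpha` towards their average; the two priors are co-updated from the
#' network's row/column similarities with the same step.
#'
#' @param motif A `motif_prior` (or TF x gene matrix).
#' @param ppi A `ppi_prior` (or TF x TF matrix).
#' @param coexpr A `coexpression` matrix (gene x gene).
#' @param alpha Learning rate in [0, 1]; `alpha = 0` is a degenerate
#'   identity update useful for testing.
#' @param tol Convergence threshold on the mean absolute change of the
#'   network between iterations.
#' @param max_iter Maximum number of iterations; `max_iter = 0` returns the
#'   normalized prior unconverged.
#' @return An object of class `aggregate_grn` with `weights` (TF x gene,
#'   z-score scale, possibly negative — the sign does not indicate
#'   activation vs. repression), `converged` and `n_iterations`.
#' @export
panda_aggregate <- function(motif, ppi, coexpr, alpha = 0.1, tol = 1e-3,
                            max_iter = 200) {
  m <- if (inherits(motif, "motif_prior")) motif$weights else as.matrix(motif)
  p <- if (inherits(ppi, "ppi_prior")) ppi$weights else as.matrix(ppi)
  co <- unclass(as.matrix(coexpr))
  if (!all(is.finite(m)) || !all(is.finite(p)) || !all(is.finite(co))) {
    stop("network inference inputs must be finite")
  }
  if (nrow(p) != nrow(m) || ncol(p) != nrow(m)) {
    stop(sprintf("PPI prior is %dx%d but motif prior has %d TFs",
                 nrow(p), ncol(p), nrow(m)))
  }
  if (nrow(co) != ncol(m) || ncol(co) != ncol(m)) {
    stop(sprintf("co-expression is %dx%d but motif prior has %d genes",
                 nrow(co), ncol(co), ncol(m)))
  }
  if (alpha < 0 || alpha > 1) stop("`alpha` must be in [0, 1]")
  if (tol <= 0) stop("`tol` must be positive")
  max_iter <- .check_count(max_iter, "max_iter", min = 0)

  w <- .znorm(m)
  pp <- .znorm(p)
  cc <- .znorm(co)
  converged <- FALSE
  it <- 0L
  while (it < max_iter) {
    it <- it + 1L
    resp <- .tanimoto(pp %*% w, rowSums(pp^2), colSums(w^2))
    avail <- .tanimoto(w %*% cc, rowSums(w^2), colSums(cc^2))
    w_new <- (1 - alpha) * w + alpha * (resp + avail) / 2
    delta <- mean(abs(w_new - w))
    w <- w_new
    wr <- rowSums(w^2)
    wc <- colSums(w^2)
    # keep the co-updated priors on the z-score scale: the Tanimoto
    # self-similarity inflates their diagonal, and without re-standardizing
    # the message passing diverges
    pp <- .znorm((1 - alpha) * pp + alpha * .tanimoto(w %*% t(w), wr, wr))
    cc <- .znorm((1 - alpha) * cc + alpha * .tanimoto(t(w) %*% w, wc, wc))
    if (delta < tol) { converged <- TRUE; break }
  }
  dimnames(w) <- dimnames(m)
  structure(list(weights = w, tf_ids = rownames(m), gene_ids = colnames(m),
                 converged = converged, n_iterations = it),
            class = "aggregate_grn")
}

#' @export
print.aggregate_grn <- function(x, ...) {
  cat(sprintf("<aggregate_grn> %d TFs x %d genes; %s after %d iteration(s)\n",
              length(x$tf_ids), length(x$gene_ids),
              if (x$converged) "converged" else "not converged", x$n_iterations))
  invisible(x)
}

#' Single-sample networks by linear interpolation
#'
#' For each sample q, reconstructs the aggregate network without it and
#' forms the sample-specific network
#' `e(q) = N * (e(all) - e(-q)) + e(-q)`,
#' assuming each sample contributes linearly to the aggregate. When the
#' aggregate estimator is a mean of per-sample contributions, this recovers
#' each sample's contribution exactly.
#'
#' @param expr An `omics_block` or matrix (features x samples, N >= 2).
#' @param network_fn Deterministic estimator: a function taking a
#'   feature x sample matrix and returning a numeric network matrix of
#'   fixed dimension. See [netfn_panda()], [netfn_masked_cor()],
#'   [netfn_contribution()], [netfn_prior_attribution()].
#' @return A `sample_network_set` (edges in column-major order of the
#'   estimator's output matrix).
#' @export
lioness_networks <- function(expr, network_fn) {
  x <- .block_values(expr)
  n <- ncol(x)
  if (n < 2) stop("leave-one-out interpolation is undefined for a single sample")
  e_all <- network_fn(x)
  weights <- matrix(0, n, length(e_all))
  for (q in seq_len(n)) {
    e_mq <- network_fn(x[, -q, drop = FALSE])
    weights[q, ] <- as.vector(n * (e_all - e_mq) + e_mq)
  }
  tf_ids <- rownames(e_all) %||% .make_ids("TF", nrow(e_all))
  gene_ids <- colnames(e_all) %||% .make_ids("G", ncol(e_all))
  sample_network_set(weights, tf_ids = tf_ids, gene_ids = gene_ids,
                     sample_ids = colnames(x))
}

#' Network estimators for single-sample interpolation
#'
#' Factory functions returning aggregate-network estimators usable as the
#' `network_fn` of [lioness_networks()] and [lioness_degrees()]:
#' \describe{
#'   \item{`netfn_panda`}{the message-passing aggregate of
#'     [panda_aggregate()] on the samples' gene co-expression;}
#'   \item{`netfn_masked_cor`}{TF-gene Pearson correlation of expression,
#'     masked by the motif prior (TF rows must be present in the
#'     expression matrix);}
#'   \item{`netfn_contribution`}{the mean over samples of per-sample
#'     contribution matrices `contrib_fn(x_q)` — a linear estimator for
#'     which the interpolation recovers contributions exactly;}
#'   \item{`netfn_prior_attribution`}{a `netfn_contribution` whose
#'     contribution attributes each gene's expression to its
#'     prior-supported regulators (edge t->g gets the expression of g when
#'     the motif supports it).}
#' }
#'
#' @param motif A `motif_prior`.
#' @param ppi A `ppi_prior`.
#' @param alpha,tol,max_iter Passed to [panda_aggregate()].
#' @param contrib_fn Function mapping one sample's feature vector to its
#'   contribution matrix.
#' @return A function suitable as `network_fn`.
#' @export
netfn_panda <- function(motif, ppi, alpha = 0.1, tol = 1e-3, max_iter = 200) {
  gene_ids <- colnames(motif$weights)
  function(x) {
    panda_aggregate(motif, ppi, compute_coexpression(x[gene_ids, , drop = FALSE]),
                    alpha = alpha, tol = tol, max_iter = max_iter)$weights
  }
}

#' @rdname netfn_panda
#' @export
netfn_masked_cor <- function(motif) {
  m <- motif$weights
  function(x) {
    co <- stats::cor(t(x[rownames(m), , drop = FALSE]),
                     t(x[colnames(m), , drop = FALSE]))
    co * m
  }
}

#' @rdname netfn_panda
#' @export
netfn_contribution <- function(contrib_fn) {
  function(x) {
    acc <- contrib_fn(x[, 1])
    n <- ncol(x)
    if (n > 1) for (q in 2:n) acc <- acc + contrib_fn(x[, q])
    acc / n
  }
}

#' @rdname netfn_panda
#' @export
netfn_prior_attribution <- function(motif) {
  m <- motif$weights
  gene_ids <- colnames(m)
  netfn_contribution(function(x) {
    m * matrix(x[gene_ids], nrow(m), ncol(m), byrow = TRUE)
  })
}

#' Network degree summaries
#'
#' The indegree of a gene is the sum of the (signed) weights of all edges
#' connecting it to its regulators; the outdegree of a TF is the sum of the
#' weights of all edges to its targets. Per sample, total indegree and
#' total outdegree both equal the total edge weight. Degrees are computed
#' on raw signed weights without thresholding; the edge-weight sign does
#' not indicate direction of regulation.
#'
#' @param networks A `sample_network_set`, or a single TF x gene matrix.
#' @return For a network set, a `degree_matrix` (samples x nodes, with
#'   `node_kind` "gene" for indegree or "tf" for outdegree); for a single
#'   matrix, a named numeric vector.
#' @export
indegree <- function(networks) UseMethod("indegree")

#' @export
indegree.sample_network_set <- function(networks) {
  n_tfs <- length(networks$tf_ids)
  n_genes <- length(networks$gene_ids)
  values <- t(apply(networks$weights, 1, function(w) {
    colSums(matrix(w, n_tfs, n_genes))
  }))
  dimnames(values) <- list(networks$sample_ids, networks$gene_ids)
  degree_matrix(values, node_kind = "gene")
}

#' @export
indegree.default <- function(networks) {
  w <- as.matrix(networks)
  stats::setNames(colSums(w), colnames(w))
}

#' @rdname indegree
#' @export
outdegree <- function(networks) UseMethod("outdegree")

#' @export
outdegree.sample_network_set <- function(networks) {
  n_tfs <- length(networks$tf_ids)
  n_genes <- length(networks$gene_ids)
  values <- t(apply(networks$weights, 1, function(w) {
    rowSums(matrix(w, n_tfs, n_genes))
  }))
  dimnames(values) <- list(networks$sample_ids, networks$tf_ids)
  degree_matrix(values, node_kind = "tf")
}

#' @export
outdegree.default <- function(networks) {
  w <- as.matrix(networks)
  stats::setNames(rowSums(w), rownames(w))
}

#' Construct a degree matrix
#'
#' @param values Samples x nodes numeric matrix.
#' @param node_kind "gene" (indegrees) or "tf" (outdegrees).
#' @return An object of class `degree_matrix`.
#' @export
degree_matrix <- function(values, node_kind = c("gene", "tf")) {
  node_kind <- match.arg(node_kind)
  values <- as.matrix(values)
  structure(list(values = values, node_kind = node_kind,
                 sample_ids = rownames(values), node_ids = colnames(values)),
            class = "degree_matrix")
}

#' @export
print.degree_matrix <- function(x, ...) {
  cat(sprintf("<degree_matrix> %s: %d samples x %d nodes\n",
              if (x$node_kind == "gene") "indegree" else "outdegree",
              nrow(x$values), ncol(x$values)))
  invisible(x)
}

#' Streamed single-sample degrees
#'
#' Computes per-sample indegrees and outdegrees via leave-one-out linear
#' interpolation without materializing the full samples x edges array:
#' each single-sample network is reduced to its degree sums as soon as it
#' is formed.
#'
#' @inheritParams lioness_networks
#' @return A list with `indegree` and `outdegree` `degree_matrix` objects.
#' @export
lioness_degrees <- function(expr, network_fn) {
  x <- .block_values(expr)
  n <- ncol(x)
  if (n < 2) stop("leave-one-out interpolation is undefined for a single sample")
  e_all <- network_fn(x)
  ind <- matrix(0, n, ncol(e_all))
  outd <- matrix(0, n, nrow(e_all))
  for (q in seq_len(n)) {
    e_mq <- network_fn(x[, -q, drop = FALSE])
    e_q <- n * (e_all - e_mq) + e_mq
    ind[q, ] <- colSums(e_q)
    outd[q, ] <- rowSums(e_q)
  }
  sample_ids <- colnames(x)
  dimnames(ind) <- list(sample_ids, colnames(e_all) %||% .make_ids("G", ncol(e_all)))
  dimnames(outd) <- list(sample_ids, rownames(e_all) %||% .make_ids("TF", nrow(e_all)))
  list(indegree = degree_matrix(ind, "gene"),
       outdegree = degree_matrix(outd, "tf"))
}

#' Serialize networks as a TSV edge table
#'
#' Writes `tf`, `gene`, `weight` (and `sample` for per-sample sets) rows.
#'
#' @param x An `aggregate_grn` or `sample_network_set`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_network_tsv <- function(x, path) {
  if (inherits(x, "aggregate_grn")) {
    df <- data.frame(tf = rep(x$tf_ids, times = length(x$gene_ids)),
                     gene = rep(x$gene_ids, each = length(x$tf_ids)),
                     weight = as.vector(x$weights))
  } else if (inherits(x, "sample_network_set")) {
    n_edges <- length(x$tf_ids) * length(x$gene_ids)
    df <- data.frame(
      sample = rep(x$sample_ids, each = n_edges),
      tf = rep(rep(x$tf_ids, times = length(x$gene_ids)), length(x$sample_ids)),
      gene = rep(rep(x$gene_ids, each = length(x$tf_ids)), length(x$sample_ids)),
      weight = as.vector(t(x$weights)))
  } else stop("unsupported network object")
  .write_tsv(df, path)
}
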