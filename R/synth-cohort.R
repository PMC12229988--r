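#' Simulate latent factor scores
#'
#' Draws i.i.d. standard-normal factor scores for a cohort and centers each
#' factor column, providing the ground-truth latent structure that the joint
#' factorization is expected to recover.
#'
#' @param n_samples Number of samples (>= 2).
#' @param k_true Number of latent factors (>= 1).
#' @param seed Optional RNG seed for reproducibility.
#' @return An object of class `latent_factors` with `scores` (samples x
#'   k_true, column-centered) and `sample_ids`.
#' @export
simulate_latent_factors <- function(n_samples, k_true, seed = NULL) {
  n_samples <- .check_count(n_samples, "n_samples", min = 2)
  k_true <- .check_count(k_true, "k_true", min = 1)
  .set_seed(seed)
  z <- matrix(stats::rnorm(n_samples * k_true), n_samples, k_true)
  z <- sweep(z, 2, colMeans(z))
  dimnames(z) <- list(.make_ids("S", n_samples), paste0("Z", seq_len(k_true)))
  structure(list(scores = z, sample_ids = rownames(z)), class = "latent_factors")
}

.factor_scores <- function(factors) {
  if (inherits(factors, "latent_factors")) factors$scores else as.matrix(factors)
}

#' Simulate one omics block from latent factors
#'
#' Generates `X = L Z_active' + E` (features x samples) with Gaussian
#' loadings `L` and Gaussian noise `E`. A fraction of constant features can
#' be injected to exercise the zero-variance filter applied before PCA.
#'
#' @param factors A `latent_factors` object (or samples x K matrix).
#' @param n_features Number of features to generate.
#' @param active_factors Indices of the factors this block loads on.
#' @param loading_scale SD of the Gaussian loading entries; either a single
#'   value or one per active factor (graded per-factor effect sizes, the
#'   scree-like spectrum real multi-omics factor models exhibit).
#' @param noise_sd SD of the additive Gaussian noise (>= 0).
#' @param inject_constant_fraction Fraction of features replaced by
#'   constants (sd = 0 across samples).
#' @param seed Optional RNG seed.
#' @param name Omic label.
#' @param loadings Optional pre-drawn loading matrix (features x
#'   length(active_factors)); used to share generating structure between
#'   replicate cohorts.
#' @return An `omics_block`; the generating loadings are attached as
#'   attribute `"loadings"` and the injected constant features as
#'   `"constant_features"`.
#' @export
simulate_omics_block <- function(factors, n_features, active_factors,
                                 loading_scale = 1, noise_sd = 0.1,
                                 inject_constant_fraction = 0, seed = NULL,
                                 name = "omic", loadings = NULL) {
  z <- .factor_scores(factors)
  n_features <- .check_count(n_features, "n_features", min = 1)
  if (noise_sd < 0) stop("`noise_sd` must be >= 0")
  inject_constant_fraction <- .check_fraction(inject_constant_fraction,
                                              "inject_constant_fraction")
  if (length(active_factors) == 0 && any(loading_scale > 0)) {
    stop("`active_factors` must be non-empty when loading_scale > 0")
  }
  if (!length(loading_scale) %in% c(1L, max(length(active_factors), 1L))) {
    stop("`loading_scale` must be a single value or one per active factor")
  }
  if (length(active_factors) > 0 &&
      (any(active_factors < 1) || any(active_factors > ncol(z)))) {
    stop("`active_factors` out of range for the supplied factors")
  }
  .set_seed(seed)
  n <- nrow(z)
  a <- length(active_factors)
  if (is.null(loadings)) {
    loadings <- matrix(stats::rnorm(n_features * max(a, 1)),
                       n_features, max(a, 1))
    loadings <- loadings %*% diag(rep_len(loading_scale, max(a, 1)),
                                  max(a, 1), max(a, 1))
  }
  x <- if (a > 0) {
    loadings[, seq_len(a), drop = FALSE] %*% t(z[, active_factors, drop = FALSE])
  } else {
    matrix(0, n_features, n)
  }
  if (noise_sd > 0) x <- x + matrix(stats::rnorm(n_features * n, 0, noise_sd),
                                    n_features, n)
  feature_ids <- .make_ids(paste0(name, "_f"), n_features)
  const_idx <- integer(0)
  n_const <- round(inject_constant_fraction * n_features)
  if (n_const > 0) {
    const_idx <- sort(sample.int(n_features, n_const))
    x[const_idx, ] <- stats::rnorm(n_const)  # one constant value per feature
  }
  block <- omics_block(x, name = name, feature_ids = feature_ids,
                       sample_ids = rownames(z))
  attr(block, "loadings") <- loadings
  attr(block, "constant_features") <- feature_ids[const_idx]
  block
}

#' Simulate regulatory priors
#'
#' Motif prior: TF x gene 0/1 matrix with i.i.d. Bernoulli entries (any TF
#' left without a supported edge is given one at a random position so the
#' prior remains usable for network inference). PPI prior: symmetric TF x TF
#' 0/1 matrix with unit diagonal.
#'
#' @param n_tfs,n_genes Numbers of TFs and genes (both >= 2).
#' @param motif_density,ppi_density Bernoulli edge probabilities in [0, 1].
#' @param seed Optional RNG seed.
#' @return A list with elements `motif` (a `motif_prior`) and `ppi`
#'   (a `ppi_prior`).
#' @export
simulate_priors <- function(n_tfs, n_genes, motif_density = 0.2,
                            ppi_density = 0.2, seed = NULL) {
  n_tfs <- .check_count(n_tfs, "n_tfs", min = 2)
  n_genes <- .check_count(n_genes, "n_genes", min = 2)
  motif_density <- .check_fraction(motif_density, "motif_density")
  ppi_density <- .check_fraction(ppi_density, "ppi_density")
  .set_seed(seed)
  m <- matrix(stats::rbinom(n_tfs * n_genes, 1, motif_density), n_tfs, n_genes)
  if (motif_density > 0) {
    for (i in which(rowSums(m) == 0)) m[i, sample.int(n_genes, 1)] <- 1
  }
  p <- matrix(0, n_tfs, n_tfs)
  up <- upper.tri(p)
  p[up] <- stats::rbinom(sum(up), 1, ppi_density)
  p <- p + t(p)
  diag(p) <- 1
  tf_ids <- .make_ids("TF", n_tfs)
  gene_ids <- .make_ids("G", n_genes)
  list(
    motif = suppressWarnings(motif_prior(m, tf_ids = tf_ids, gene_ids = gene_ids)),
    ppi = ppi_prior(p, tf_ids = tf_ids)
  )
}

#' Simulate factor-dependent single-sample networks
#'
#' Per sample q, edge weights on the motif-supported edges are
#' `w_q(t, g) = baseline + edge_effect * z_q1 * u_t * v_g + noise`, with
#' fixed non-negative unit-norm TF/gene patterns `u`, `v`; unsupported edges
#' have weight 0. A coupled gene-expression block is emitted whose gene
#' values are the column sums of the incoming edge weights plus noise, so
#' expression carries the same latent signal as the networks.
#'
#' @param factors A `latent_factors` object; the first factor drives the
#'   edge weights.
#' @param motif A `motif_prior`.
#' @param edge_effect Strength of the factor-to-edge coupling.
#' @param noise_sd SD of edge-weight noise on supported edges.
#' @param baseline Baseline edge weight on supported edges.
#' @param expr_noise_sd SD of the expression measurement noise.
#' @param seed Optional RNG seed.
#' @param u,v Optional pre-drawn unit-norm patterns (shared across
#'   replicate cohorts).
#' @return A list with `networks` (a `sample_network_set`), `expression`
#'   (an `omics_block` over the motif's genes) and `patterns` (u, v).
#' @export
simulate_factor_dependent_networks <- function(factors, motif, edge_effect = 1,
                                               noise_sd = 0.1, baseline = 1,
                                               expr_noise_sd = 0.1, seed = NULL,
                                               u = NULL, v = NULL) {
  z <- .factor_scores(factors)
  m <- motif$weights
  if (sum(m != 0) == 0) stop("motif prior has no supported edges")
  .set_seed(seed)
  n_tfs <- nrow(m)
  n_genes <- ncol(m)
  n <- nrow(z)
  if (is.null(u)) { u <- abs(stats::rnorm(n_tfs)); u <- u / sqrt(sum(u^2)) }
  if (is.null(v)) { v <- abs(stats::rnorm(n_genes)); v <- v / sqrt(sum(v^2)) }
  uv <- outer(u, v)
  weights <- matrix(0, n, n_tfs * n_genes)
  expr <- matrix(0, n_genes, n)
  for (q in seq_len(n)) {
    w <- m * (baseline + edge_effect * z[q, 1] * uv)
    if (noise_sd > 0) {
      w <- w + m * matrix(stats::rnorm(n_tfs * n_genes, 0, noise_sd), n_tfs, n_genes)
    }
    weights[q, ] <- as.vector(w)
    expr[, q] <- colSums(w)
  }
  if (expr_noise_sd > 0) {
    expr <- expr + matrix(stats::rnorm(length(expr), 0, expr_noise_sd),
                          n_genes, n)
  }
  networks <- sample_network_set(weights, tf_ids = rownames(m),
                                 gene_ids = colnames(m),
                                 sample_ids = rownames(z))
  expression <- omics_block(expr, name = "expression",
                            feature_ids = colnames(m), sample_ids = rownames(z))
  list(networks = networks, expression = expression, patterns = list(u = u, v = v))
}

#' Simulate survival outcomes from latent factors
#'
#' Event times are exponential with rate `baseline_rate * exp(beta' z)`
#' (a proportional-hazards model); censoring times are exponential with
#' rate `censor_rate`. The observed time is the minimum of the two.
#'
#' @param factors A `latent_factors` object (or samples x K matrix).
#' @param beta Hazard log-coefficients, one per latent factor.
#' @param baseline_rate,censor_rate Positive exponential rates.
#' @param seed Optional RNG seed.
#' @return A `survival_table`.
#' @export
simulate_survival <- function(factors, beta, baseline_rate = 0.1,
                              censor_rate = 0.05, seed = NULL) {
  z <- .factor_scores(factors)
  baseline_rate <- .check_positive(baseline_rate, "baseline_rate")
  censor_rate <- .check_positive(censor_rate, "censor_rate")
  if (length(beta) != ncol(z)) stop("`beta` must have one entry per factor")
  .set_seed(seed)
  n <- nrow(z)
  rate <- baseline_rate * exp(drop(z %*% beta))
  t_event <- stats::rexp(n, rate)
  t_cens <- stats::rexp(n, censor_rate)
  survival_table(rownames(z) %||% .make_ids("S", n),
                 pmin(t_event, t_cens), as.integer(t_event <= t_cens))
}

#' Default configuration for the synthetic cohort generator
#'
#' Desk-scale study conditions: 150 samples, 4 latent factors, three omics
#' blocks (a 300-gene expression block generated from the factor-dependent
#' networks, plus 150- and 400-feature independent blocks), a 40 TF x 300
#' gene motif prior, and survival driven by the first factor, which acts on
#' the regulatory networks.
#'
#' @param ... Named overrides of the defaults (matched by name, shallow).
#' @return A configuration list understood by [simulate_cohort()].
#' @export
cohort_config <- function(...) {
  config <- list(
    n_samples = 150,
    k_true = 4,
    seed = 1,
    structure_seed = NULL,  # defaults to `seed`; fix it to share generative truth
    omics = list(
      mirna = list(n_features = 150, active_factors = c(2, 3),
                   loading_scale = 1, noise_sd = 0.5,
                   inject_constant_fraction = 0),
      methylation = list(n_features = 400, active_factors = c(3, 4),
                         loading_scale = 1, noise_sd = 0.5,
                         inject_constant_fraction = 0)
    ),
    network = list(n_tfs = 40, n_genes = 300, motif_density = 0.2,
                   ppi_density = 0.2, edge_effect = 1, noise_sd = 0.1,
                   baseline = 1, expr_noise_sd = 0.1),
    beta = c(1, 0, 0, 0),
    baseline_rate = 0.1,
    censor_rate = 0.05,
    clinical = list(binary_factor = 2, multi_factor = 3)
  )
  overrides <- list(...)
  for (nm in names(overrides)) config[[nm]] <- overrides[[nm]]
  config
}

#' Simulate a complete synthetic multi-omics cohort
#'
#' Bundles latent factors, omics blocks, regulatory priors, factor-dependent
#' single-sample networks with a coupled expression block, survival, and
#' clinical features discretized from selected factors. The `structure_seed`
#' fixes the generative structure (priors, loading matrices, edge patterns)
#' independently of the sample-level seed, so replicate cohorts sharing the
#' same truth can be drawn.
#'
#' @param config A list from [cohort_config()].
#' @return An object of class `synthetic_cohort` with elements `omics`
#'   (named list of `omics_block`), `motif_prior`, `ppi_prior`, `networks`
#'   (true `sample_network_set`), `survival`, `clinical` and `truth`
#'   (factors, loadings, patterns, beta).
#' @export
simulate_cohort <- function(config = cohort_config()) {
  seed <- .check_count(config$seed, "seed", min = 0)
  structure_seed <- config$structure_seed %||% seed
  k_true <- .check_count(config$k_true, "k_true", min = 1)
  if (length(config$beta) != k_true) stop("`beta` must have `k_true` entries")

  # structural components, fixed by structure_seed
  net_cfg <- config$network
  priors <- simulate_priors(net_cfg$n_tfs, net_cfg$n_genes,
                            net_cfg$motif_density, net_cfg$ppi_density,
                            seed = structure_seed)
  .set_seed(structure_seed + 1)
  u <- abs(stats::rnorm(net_cfg$n_tfs)); u <- u / sqrt(sum(u^2))
  v <- abs(stats::rnorm(net_cfg$n_genes)); v <- v / sqrt(sum(v^2))
  loadings <- list()
  for (nm in names(config$omics)) {
    oc <- config$omics[[nm]]
    loadings[[nm]] <- matrix(
      stats::rnorm(oc$n_features * length(oc$active_factors), 0, oc$loading_scale),
      oc$n_features, length(oc$active_factors))
  }

  # sample-level components
  factors <- simulate_latent_factors(config$n_samples, k_true, seed = seed + 1)
  net <- simulate_factor_dependent_networks(
    factors, priors$motif, edge_effect = net_cfg$edge_effect,
    noise_sd = net_cfg$noise_sd, baseline = net_cfg$baseline,
    expr_noise_sd = net_cfg$expr_noise_sd, seed = seed + 2, u = u, v = v)
  omics <- list(expression = net$expression)
  i <- 3
  for (nm in names(config$omics)) {
    oc <- config$omics[[nm]]
    omics[[nm]] <- simulate_omics_block(
      factors, oc$n_features, oc$active_factors,
      loading_scale = oc$loading_scale, noise_sd = oc$noise_sd,
      inject_constant_fraction = oc$inject_constant_fraction %||% 0,
      seed = seed + i, name = nm, loadings = loadings[[nm]])
    i <- i + 1
  }
  surv <- simulate_survival(factors, config$beta,
                            baseline_rate = config$baseline_rate,
                            censor_rate = config$censor_rate, seed = seed + 10)
  z <- factors$scores
  bf <- config$clinical$binary_factor
  mf <- config$clinical$multi_factor
  clinical <- data.frame(
    group_bin = ifelse(z[, bf] > stats::median(z[, bf]), "high", "low"),
    grade = as.character(cut(z[, mf],
                             stats::quantile(z[, mf], c(0, 1 / 3, 2 / 3, 1)),
                             labels = c("G1", "G2", "G3"),
                             include.lowest = TRUE)),
    row.names = rownames(z), stringsAsFactors = FALSE)

  cohort <- structure(list(
    omics = omics,
    motif_prior = priors$motif,
    ppi_prior = priors$ppi,
    networks = net$networks,
    survival = surv,
    clinical = clinical,
    truth = list(factors = factors, loadings = loadings,
                 patterns = net$patterns, beta = config$beta),
    config = config
  ), class = "synthetic_cohort")
  .validate_cohort(cohort)
  cohort
}

.validate_cohort <- function(cohort) {
  ids <- cohort$truth$factors$sample_ids
  for (nm in names(cohort$omics)) {
    if (!identical(colnames(cohort$omics[[nm]]$values), ids)) {
      stop(sprintf("internal consistency error: sample ids of block '%s' differ", nm))
    }
  }
  if (!identical(cohort$survival$sample_id, ids)) {
    stop("internal consistency error: survival sample ids differ")
  }
  if (!identical(rownames(cohort$clinical), ids)) {
    stop("internal consistency error: clinical sample ids differ")
  }
  invisible(cohort)
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat(sprintf("<synthetic_cohort> %d samples, %d true factors\n",
              length(x$truth$factors$sample_ids), ncol(x$truth$factors$scores)))
  for (b in x$omics) print(b)
  cat(sprintf("  motif prior: %d TFs x %d genes; survival events: %d\n",
              nrow(x$motif_prior$weights), ncol(x$motif_prior$weights),
              sum(x$survival$event)))
  invisible(x)
}

#' Write a synthetic cohort to TSV files with a YAML manifest
#'
#' Serializes omics blocks, priors, survival, clinical features and the true
#' factor scores as TSV, and writes `manifest.yaml` listing paths and the
#' generating seed. Per-sample network weights are not serialized (they are
#' reproducible from the config).
#'
#' @param cohort A `synthetic_cohort`.
#' @param dir Output directory (created if needed).
#' @return The manifest path, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- list()
  for (nm in names(cohort$omics)) {
    paths$omics[[nm]] <- file.path(dir, paste0("omics_", nm, ".tsv"))
    write_omics_tsv(cohort$omics[[nm]], paths$omics[[nm]])
  }
  paths$motif <- file.path(dir, "motif_prior.tsv")
  .write_matrix_tsv(cohort$motif_prior$weights, paths$motif, id_col = "tf_id")
  paths$ppi <- file.path(dir, "ppi_prior.tsv")
  .write_matrix_tsv(cohort$ppi_prior$weights, paths$ppi, id_col = "tf_id")
  paths$survival <- file.path(dir, "survival.tsv")
  write_survival_tsv(cohort$survival, paths$survival)
  paths$clinical <- file.path(dir, "clinical.tsv")
  clin <- data.frame(sample_id = rownames(cohort$clinical), cohort$clinical,
                     stringsAsFactors = FALSE)
  .write_tsv(clin, paths$clinical)
  paths$truth_factors <- file.path(dir, "truth_factors.tsv")
  .write_matrix_tsv(cohort$truth$factors$scores, paths$truth_factors,
                    id_col = "sample_id")
  manifest <- list(seed = cohort$config$seed,
                   structure_seed = cohort$config$structure_seed %||% cohort$config$seed,
                   paths = lapply(paths, function(p) {
                     if (is.list(p)) lapply(p, basename) else basename(p)
                   }))
  manifest_path <- file.path(dir, "manifest.yaml")
  yaml::write_yaml(manifest, manifest_path)
  invisible(manifest_path)
}

#' Read a cohort back from a manifest written by [write_cohort()]
#'
#' @param manifest_path Path to `manifest.yaml`.
#' @return A list with `omics`, `motif_prior`, `ppi_prior`, `survival`,
#'   `clinical` and `truth` (factor scores only); per-sample networks are
#'   not serialized and come back as `NULL`.
#' @export
read_cohort <- function(manifest_path) {
  if (!file.exists(manifest_path)) stop("manifest not found: ", manifest_path)
  manifest <- yaml::read_yaml(manifest_path)
  dir <- dirname(manifest_path)
  omics <- lapply(names(manifest$paths$omics), function(nm) {
    read_omics_tsv(file.path(dir, manifest$paths$omics[[nm]]), name = nm)
  })
  names(omics) <- names(manifest$paths$omics)
  clin_df <- utils::read.table(file.path(dir, manifest$paths$clinical),
                               sep = "\t", header = TRUE, stringsAsFactors = FALSE)
  clinical <- clin_df[, -1, drop = FALSE]
  rownames(clinical) <- clin_df$sample_id
  list(
    omics = omics,
    motif_prior = suppressWarnings(
      motif_prior(.read_matrix_tsv(file.path(dir, manifest$paths$motif)))),
    ppi_prior = ppi_prior(.read_matrix_tsv(file.path(dir, manifest$paths$ppi))),
    networks = NULL,
    survival = read_survival_tsv(file.path(dir, manifest$paths$survival)),
    clinical = clinical,
    truth = list(scores = .read_matrix_tsv(file.path(dir, manifest$paths$truth_factors))),
    seed = manifest$seed
  )
}
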