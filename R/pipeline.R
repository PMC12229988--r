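#' Analysis parameters for the factorization pipeline
#'
#' Defaults mirror the study conditions: cumulative variance threshold
#' 0.85 with a floor of 20 PCs per block, K = 5 factors, the deterministic
#' `mfa_svd` backend with seed 13, and an SAF threshold of FDR < 0.05.
#'
#' @param threshold,floor PCA selection parameters ([select_num_pcs()]).
#' @param k Number of joint factors.
#' @param method Factorization backend ([fit_jdr()]).
#' @param seed Backend seed.
#' @param fdr_threshold SAF significance threshold.
#' @param center,scale PCA preprocessing flags.
#' @return A named list of parameters.
#' @export
jdr_params <- function(threshold = 0.85, floor = 20, k = 5,
                       method = "mfa_svd", seed = 13, fdr_threshold = 0.05,
                       center = TRUE, scale = TRUE) {
  list(threshold = threshold, floor = floor, k = k, method = method,
       seed = seed, fdr_threshold = fdr_threshold, center = center,
       scale = scale)
}

.as_sample_ids <- function(x) {
  if (is.character(x)) return(x)
  if (inherits(x, "omics_block")) return(colnames(x$values))
  if (inherits(x, "survival_table")) return(x$sample_id)
  if (inherits(x, "degree_matrix")) return(rownames(x$values))
  if (inherits(x, "factor_model")) return(rownames(x$scores))
  if (is.matrix(x)) return(colnames(x))
  if (is.data.frame(x)) return(rownames(x))
  stop("cannot extract sample identifiers from an object of class ",
       paste(class(x), collapse = "/"))
}

#' Complete-case sample selection
#'
#' Returns the samples present in every supplied input (omics blocks,
#' degree matrices, survival and clinical tables); the factorization
#' requires every sample to be observed in every block. Per-input drop
#' counts are attached as attribute `"dropped"`.
#'
#' @param ... Inputs, or a single list of inputs.
#' @return Character vector of shared sample identifiers (>= 4, else an
#'   error).
#' @export
complete_case_samples <- function(...) {
  inputs <- list(...)
  if (length(inputs) == 1 && is.list(inputs[[1]]) &&
      !inherits(inputs[[1]], c("omics_block", "survival_table",
                               "degree_matrix", "factor_model", "data.frame"))) {
    inputs <- inputs[[1]]
  }
  id_sets <- lapply(inputs, .as_sample_ids)
  shared <- Reduce(intersect, id_sets)
  if (length(shared) < 4) {
    stop("fewer than 4 samples shared across all inputs")
  }
  dropped <- vapply(id_sets, function(ids) length(setdiff(ids, shared)), integer(1))
  names(dropped) <- names(inputs) %||% paste0("input", seq_along(inputs))
  total <- sum(dropped)
  if (total > 0) {
    message(sprintf("complete-case selection: %d sample(s) dropped across inputs", total))
  }
  attr(shared, "dropped") <- dropped
  shared
}

.subset_block <- function(block, ids) {
  omics_block(block$values[, ids, drop = FALSE], name = block$name)
}

.degree_as_block <- function(deg, name) {
  omics_block(t(deg$values), name = name)
}

#' Run one model variant
#'
#' Composes the full path for a single configuration of input blocks:
#' complete-case sample selection, zero-variance filtering, per-block PCA
#' filtering, joint factorization, survival association, and back-mapping
#' of factor weights to original features. Variants: `"omics"` (omics
#' blocks only), `"indegree"`, `"outdegree"` (omics plus that degree
#' matrix as an extra block), `"both"`. Degree matrices pass through the
#' same sd-filter / PCA-filter path as the omics blocks.
#'
#' @param omics Named list of `omics_block` objects.
#' @param survival A `survival_table`.
#' @param variant One of "omics", "indegree", "outdegree", "both".
#' @param degrees List with `indegree` / `outdegree` `degree_matrix`
#'   entries (required unless `variant = "omics"`).
#' @param params Parameters from [jdr_params()].
#' @return An object of class `variant_result`: `variant`, `model`
#'   (`factor_model`), `assoc` (`survival_assoc_table`), `weights`
#'   (back-mapped per-block feature weights), `blocks` (filtered blocks),
#'   `samples`.
#' @export
run_variant <- function(omics, survival, variant = c("omics", "indegree",
                                                     "outdegree", "both"),
                        degrees = NULL, params = jdr_params()) {
  variant <- match.arg(variant)
  blocks <- omics
  if (variant != "omics") {
    if (is.null(degrees)) stop("degree matrices are required for variant '", variant, "'")
    if (variant %in% c("indegree", "both")) {
      blocks$indegree <- .degree_as_block(degrees$indegree, "indegree")
    }
    if (variant %in% c("outdegree", "both")) {
      blocks$outdegree <- .degree_as_block(degrees$outdegree, "outdegree")
    }
  }
  ids <- complete_case_samples(c(blocks, list(survival = survival)))
  blocks <- lapply(blocks, .subset_block, ids = ids)
  surv <- survival[match(ids, survival$sample_id), , drop = FALSE]
  filtered <- lapply(blocks, function(b) {
    filter_block(b, threshold = params$threshold, floor = params$floor,
                 center = params$center, scale = params$scale)
  })
  model <- fit_jdr(filtered, K = params$k, method = params$method,
                   seed = params$seed)
  assoc <- survival_assoc_table(model, surv,
                                fdr_threshold = params$fdr_threshold)
  weights <- backmap_model(model, filtered)
  structure(list(variant = variant, model = model, assoc = assoc,
                 weights = weights, blocks = filtered, samples = ids),
            class = "variant_result")
}

#' @export
print.variant_result <- function(x, ...) {
  cat(sprintf("<variant_result> '%s': %d factors, %d SAF(s)\n",
              x$variant, x$model$K, sum(x$assoc$saf)))
  invisible(x)
}

#' Compare survival association across model variants
#'
#' Tabulates, per variant and factor, the Cox p-value, FDR and
#' `-log10(FDR)` (floored at the smallest representable double), together
#' with per-variant SAF counts and the best (smallest) FDR. Variant order
#' follows the input order.
#'
#' @param results Named list of `variant_result` objects (>= 2).
#' @return An object of class `model_comparison` with `per_factor` and
#'   `summary` data frames.
#' @export
compare_models <- function(results) {
  if (length(results) < 2) stop("at least two variants are required")
  if (is.null(names(results))) {
    names(results) <- vapply(results, `[[`, character(1), "variant")
  }
  per_factor <- do.call(rbind, lapply(names(results), function(nm) {
    a <- results[[nm]]$assoc
    data.frame(variant = nm, factor = a$factor, p = a$p, fdr = a$fdr,
               neglog10_fdr = -log10(pmax(a$fdr, .Machine$double.xmin)),
               saf = a$saf, stringsAsFactors = FALSE)
  }))
  summary <- do.call(rbind, lapply(names(results), function(nm) {
    a <- results[[nm]]$assoc
    data.frame(variant = nm, saf_count = sum(a$saf), best_fdr = min(a$fdr),
               stringsAsFactors = FALSE)
  }))
  rownames(per_factor) <- rownames(summary) <- NULL
  structure(list(per_factor = per_factor, summary = summary),
            class = "model_comparison")
}

#' @export
print.model_comparison <- function(x, ...) {
  cat("<model_comparison>\n")
  print(x$summary)
  invisible(x)
}

#' Top-TF overlap between two analyses
#'
#' Replication-style comparison: takes the survival-associated factors of
#' two variant results, selects the top TFs by absolute back-mapped
#' outdegree weight in each, and tests whether the overlap of the two TF
#' sets is larger than expected by chance over the shared TF universe.
#'
#' @param res_a,res_b `variant_result` objects whose blocks include an
#'   outdegree block.
#' @param n_top TFs per survival-associated factor (default 20).
#' @param alternative Passed to [overlap_fisher()].
#' @return A list with the two [top_tfs()] selections and the
#'   `tf_overlap` test.
#' @export
compare_top_tfs <- function(res_a, res_b, n_top = 20,
                            alternative = "greater") {
  for (r in list(res_a, res_b)) {
    if (is.null(r$weights$outdegree)) {
      stop("both results must carry back-mapped outdegree weights")
    }
  }
  saf_a <- which(res_a$assoc$saf)
  saf_b <- which(res_b$assoc$saf)
  if (length(saf_a) == 0 || length(saf_b) == 0) {
    stop("no survival-associated factors in one of the results")
  }
  universe <- intersect(rownames(res_a$weights$outdegree),
                        rownames(res_b$weights$outdegree))
  top_a <- top_tfs(res_a$weights$outdegree, saf_a, n_top = n_top)
  top_b <- top_tfs(res_b$weights$outdegree, saf_b, n_top = n_top)
  test <- overlap_fisher(top_a$union, top_b$union, universe,
                         alternative = alternative)
  list(top_a = top_a, top_b = top_b, overlap = test)
}

#' Read a pipeline configuration from YAML
#'
#' @param path Path to a YAML file whose keys mirror the arguments of
#'   [run_pipeline()] (`simulate`, `manifest`, `variants`, `params`,
#'   `network_fn`, `expression_block`, `omics_blocks`, `gmt`, `outdir`).
#' @return The configuration list.
#' @export
read_pipeline_config <- function(path) {
  if (!file.exists(path)) stop("configuration file not found: ", path)
  yaml::read_yaml(path)
}

#' Run the end-to-end analysis
#'
#' From a configuration (list or YAML path), obtains a cohort (simulated
#' via [simulate_cohort()] or read from a manifest), infers single-sample
#' network degrees from the designated expression block by leave-one-out
#' linear interpolation, runs the requested model variants, compares their
#' survival associations, and (optionally) performs preranked enrichment
#' of the back-mapped indegree weights of the survival-associated factors
#' against a GMT collection.
#'
#' Configuration keys: `simulate` (overrides for [cohort_config()]) or
#' `manifest` (path from [write_cohort()]); `variants` (default all four);
#' `params` (overrides for [jdr_params()]); `network_fn` ("attribution",
#' "cor" or "panda"); `expression_block` (block used for network
#' inference, default "expression"); `omics_blocks` (blocks used as omics
#' input, default all); `gmt` (optional GMT path); `gsea` (n_perm,
#' min_size, max_size); `outdir` (optional output directory).
#'
#' @param config Configuration list or path to a YAML file.
#' @return An object of class `pipeline_result`: `cohort`, `degrees`,
#'   `results` (per variant), `comparison`, `enrichment` (or NULL),
#'   `log` (character vector of stage records).
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- read_pipeline_config(config)
  log <- character(0)
  note <- function(...) {
    log <<- c(log, sprintf("[%s] %s", format(Sys.time(), "%H:%M:%S"),
                           sprintf(...)))
  }

  if (!is.null(config$manifest)) {
    if (!file.exists(config$manifest)) {
      stop("input path does not exist: ", config$manifest)
    }
    cohort <- read_cohort(config$manifest)
    note("loaded cohort from %s", config$manifest)
  } else {
    sim <- do.call(cohort_config, config$simulate %||% list())
    cohort <- simulate_cohort(sim)
    note("simulated cohort: %d samples, seed %d", sim$n_samples, sim$seed)
  }

  params <- do.call(jdr_params, config$params %||% list())
  variants <- config$variants %||% c("omics", "indegree", "outdegree", "both")
  expr_name <- config$expression_block %||% "expression"
  omics_names <- config$omics_blocks %||% names(cohort$omics)
  omics <- cohort$omics[omics_names]

  degrees <- NULL
  if (any(variants != "omics")) {
    if (!expr_name %in% names(cohort$omics)) {
      stop("expression block '", expr_name, "' not found in the cohort")
    }
    nf_id <- config$network_fn %||% "attribution"
    network_fn <- switch(nf_id,
      attribution = netfn_prior_attribution(cohort$motif_prior),
      cor = netfn_masked_cor(cohort$motif_prior),
      panda = netfn_panda(cohort$motif_prior, cohort$ppi_prior),
      stop("unknown network_fn: ", nf_id))
    degrees <- lioness_degrees(cohort$omics[[expr_name]], network_fn)
    note("inferred single-sample degrees ('%s' estimator) from block '%s'",
         nf_id, expr_name)
  }

  results <- list()
  for (v in variants) {
    results[[v]] <- run_variant(omics, cohort$survival, variant = v,
                                degrees = degrees, params = params)
    note("variant '%s': k_selected = %s; %d SAF(s)", v,
         paste(vapply(results[[v]]$blocks, `[[`, integer(1), "k_selected"),
               collapse = "/"),
         sum(results[[v]]$assoc$saf))
  }
  comparison <- if (length(results) >= 2) compare_models(results) else NULL

  enrichment <- NULL
  if (!is.null(config$gmt)) {
    if (!file.exists(config$gmt)) stop("input path does not exist: ", config$gmt)
    sets <- read_gmt(config$gmt)
    target <- if ("both" %in% names(results)) results$both else results[[length(results)]]
    saf <- which(target$assoc$saf)
    if (length(saf) > 0 && !is.null(target$weights$indegree)) {
      gcfg <- config$gsea %||% list()
      enrichment <- lapply(saf, function(k) {
        w <- target$weights$indegree[, k]
        gsea_preranked(w, sets,
                       n_perm = gcfg$n_perm %||% 1000,
                       min_size = gcfg$min_size %||% 15,
                       max_size = gcfg$max_size %||% 500,
                       seed = params$seed)
      })
      names(enrichment) <- target$assoc$factor[saf]
      note("enrichment computed for %d SAF(s)", length(saf))
    } else {
      note("enrichment skipped: no SAFs or no indegree weights")
    }
  }

  out <- structure(list(cohort = cohort, degrees = degrees, results = results,
                        comparison = comparison, enrichment = enrichment,
                        log = log),
                   class = "pipeline_result")
  if (!is.null(config$outdir)) .write_pipeline_outputs(out, config$outdir)
  out
}

.write_pipeline_outputs <- function(out, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (v in names(out$results)) {
    vdir <- file.path(dir, v)
    dir.create(vdir, showWarnings = FALSE, recursive = TRUE)
    write_factor_model(out$results[[v]]$model, vdir)
    .write_tsv(out$results[[v]]$assoc, file.path(vdir, "survival_assoc.tsv"))
    for (nm in names(out$results[[v]]$weights)) {
      .write_matrix_tsv(out$results[[v]]$weights[[nm]],
                        file.path(vdir, paste0("feature_weights_", nm, ".tsv")),
                        id_col = "feature_id")
    }
  }
  if (!is.null(out$comparison)) {
    .write_tsv(out$comparison$per_factor, file.path(dir, "comparison_per_factor.tsv"))
    .write_tsv(out$comparison$summary, file.path(dir, "comparison_summary.tsv"))
  }
  writeLines(out$log, file.path(dir, "run_log.txt"))
  invisible(dir)
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat(sprintf("<pipeline_result> %d variant(s)\n", length(x$results)))
  if (!is.null(x$comparison)) print(x$comparison$summary)
  invisible(x)
}
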