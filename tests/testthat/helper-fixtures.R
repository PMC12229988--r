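# shared fixture builders; everything is generated in code at test time

# small cohort for fast pipeline-level tests
small_cohort_config <- function(seed = 1, ...) {
  base <- cohort_config(
    n_samples = 100,
    omics = list(
      mirna = list(n_features = 60, active_factors = c(2, 3),
                   loading_scale = 1, noise_sd = 0.5,
                   inject_constant_fraction = 0),
      methylation = list(n_features = 80, active_factors = c(3, 4),
                         loading_scale = 1, noise_sd = 0.5,
                         inject_constant_fraction = 0)
    ),
    network = list(n_tfs = 25, n_genes = 120, motif_density = 0.2,
                   ppi_density = 0.2, edge_effect = 1, noise_sd = 0.1,
                   baseline = 1, expr_noise_sd = 0.1),
    seed = seed
  )
  overrides <- list(...)
  for (nm in names(overrides)) base[[nm]] <- overrides[[nm]]
  base
}

# degrees inferred from a cohort's expression block with the linear
# prior-attribution estimator
cohort_degrees <- function(cohort) {
  lioness_degrees(cohort$omics$expression,
                  netfn_prior_attribution(cohort$motif_prior))
}

write_temp_gmt <- function(lines) {
  path <- tempfile(fileext = ".gmt")
  writeLines(lines, path)
  path
}

# independent Pearson correlation, textbook formula, one pair at a time
pearson_oracle <- function(x, y) {
  n <- length(x)
  num <- sum((x - mean(x)) * (y - mean(y)))
  den <- sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  num / den
}

expect_matrix_equal <- function(a, b, tol = 1e-10) {
  expect_lt(max(abs(unclass(a) - unclass(b))), tol)
}
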