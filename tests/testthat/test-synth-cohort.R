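test_that("latent factor scores are centered, reproducible, and unit-scale", {
  z <- simulate_latent_factors(100, 3, seed = 1)
  expect_equal(dim(z$scores), c(100, 3))
  expect_lt(max(abs(colMeans(z$scores))), 1e-12)

  z1 <- simulate_latent_factors(50, 2, seed = 7)
  z2 <- simulate_latent_factors(50, 2, seed = 7)
  expect_identical(z1$scores, z2$scores)

  # sampling sd of the sample sd at n = 1000 is ~0.022; [0.9, 1.1] is > 4 sd
  z3 <- simulate_latent_factors(1000, 2, seed = 3)
  sds <- apply(z3$scores, 2, sd)
  expect_true(all(sds > 0.9 & sds < 1.1))

  expect_error(simulate_latent_factors(1, 2), "n_samples")
  expect_error(simulate_latent_factors(10, 0), "k_true")
})

test_that("omics blocks follow the factor model and inject constants", {
  z <- simulate_latent_factors(40, 3, seed = 2)
  # noiseless single-factor block: every feature is a scalar multiple of it
  b <- simulate_omics_block(z, 12, active_factors = 2, noise_sd = 0, seed = 5)
  ratios <- apply(b$values, 1, function(f) {
    r <- f / z$scores[, 2]
    max(r) - min(r)
  })
  expect_lt(max(ratios), 1e-10)

  b2 <- simulate_omics_block(z, 50, 1, noise_sd = 0.1,
                             inject_constant_fraction = 0.1, seed = 6)
  n_const <- sum(apply(b2$values, 1, sd) == 0)
  expect_identical(n_const, 5L)

  expect_error(simulate_omics_block(z, 10, integer(0), loading_scale = 1),
               "active_factors")
})

test_that("a low-noise single-factor block's first PC recovers the factor", {
  z <- simulate_latent_factors(60, 2, seed = 9)
  b <- simulate_omics_block(z, 500, 1, loading_scale = 1, noise_sd = 0.1,
                            seed = 10)
  pca <- fit_pca(b, scale = FALSE)
  expect_gte(abs(cor(pca$scores[, 1], z$scores[, 1])), 0.99)
})

test_that("simulated priors have the promised structure and density", {
  pr <- simulate_priors(5, 8, motif_density = 1, ppi_density = 0.5, seed = 1)
  expect_true(all(pr$motif$weights == 1))
  p <- pr$ppi$weights
  expect_identical(p, t(p))
  expect_true(all(diag(p) == 1))

  pr2 <- simulate_priors(50, 200, motif_density = 0.3, seed = 11)
  k <- sum(pr2$motif$weights)
  # binomial 99% interval for 10000 trials at p = 0.3
  bounds <- qbinom(c(0.005, 0.995), 50 * 200, 0.3)
  expect_gte(k, bounds[1])
  expect_lte(k, bounds[2])

  expect_error(simulate_priors(1, 10), "n_tfs")
  expect_error(simulate_priors(10, 1), "n_genes")
})

test_that("factor-dependent networks couple edge weights to the first factor", {
  z <- simulate_latent_factors(30, 2, seed = 3)
  pr <- simulate_priors(8, 20, motif_density = 0.4, seed = 4)

  net0 <- simulate_factor_dependent_networks(z, pr$motif, edge_effect = 0,
                                             noise_sd = 0, seed = 5)
  expect_lt(max(apply(net0$networks$weights, 2, function(col) diff(range(col)))),
            1e-12)

  net1 <- simulate_factor_dependent_networks(z, pr$motif, edge_effect = 1,
                                             noise_sd = 0, seed = 5)
  total <- rowSums(net1$networks$weights)
  fit <- lm(total ~ z$scores[, 1])
  expect_lt(max(abs(residuals(fit))), 1e-9)  # affine in z1

  z2 <- simulate_latent_factors(200, 2, seed = 6)
  pr2 <- simulate_priors(40, 300, motif_density = 0.2, seed = 7)
  net2 <- simulate_factor_dependent_networks(z2, pr2$motif, edge_effect = 1,
                                             noise_sd = 0.1, seed = 8)
  expect_gte(cor(z2$scores[, 1], rowSums(net2$networks$weights)), 0.9)
})

test_that("network-coupled expression equals incoming edge-weight sums", {
  z <- simulate_latent_factors(20, 2, seed = 13)
  pr <- simulate_priors(6, 15, motif_density = 0.5, seed = 13)
  net <- simulate_factor_dependent_networks(z, pr$motif, edge_effect = 1,
                                            noise_sd = 0.1, expr_noise_sd = 0,
                                            seed = 14)
  ind <- indegree(net$networks)
  expect_matrix_equal(t(net$expression$values), ind$values, tol = 1e-10)
})

test_that("survival simulation respects censoring and hazard direction", {
  z <- simulate_latent_factors(100, 2, seed = 4)
  s <- simulate_survival(z, c(0.5, 0), censor_rate = 1e-12, seed = 5)
  expect_true(all(s$event == 1))

  # larger hazard shortens time: Kendall tau between z1 and event times < 0
  z2 <- simulate_latent_factors(500, 2, seed = 6)
  s2 <- simulate_survival(z2, c(1, 0), baseline_rate = 0.1,
                          censor_rate = 1e-12, seed = 7)
  expect_lt(cor(z2$scores[, 1], s2$time, method = "kendall"), 0)

  expect_error(simulate_survival(z, c(1, 0), baseline_rate = 0), "baseline_rate")
  expect_error(simulate_survival(z, c(1)), "beta")
})

test_that("raising the censoring rate never adds events (common random numbers)", {
  z <- simulate_latent_factors(200, 2, seed = 8)
  events <- sapply(c(0.01, 0.05, 0.2, 1), function(cr) {
    sum(simulate_survival(z, c(1, 0), censor_rate = cr, seed = 99)$event)
  })
  expect_true(all(diff(events) <= 0))
})

test_that("simulated cohorts are internally consistent and deterministic on disk", {
  cfg <- small_cohort_config(seed = 3)
  co <- simulate_cohort(cfg)
  ids <- co$truth$factors$sample_ids
  for (b in co$omics) expect_identical(colnames(b$values), ids)
  expect_identical(co$survival$sample_id, ids)
  expect_identical(rownames(co$clinical), ids)
  expect_identical(ncol(co$truth$factors$scores), 4L)

  cfg5 <- small_cohort_config(seed = 3, k_true = 5, beta = c(1, 0, 0, 0, 0))
  expect_identical(ncol(simulate_cohort(cfg5)$truth$factors$scores), 5L)

  d1 <- file.path(tempdir(), "cohort_a")
  d2 <- file.path(tempdir(), "cohort_b")
  write_cohort(co, d1)
  write_cohort(simulate_cohort(cfg), d2)
  for (f in list.files(d1)) {
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)),
                     info = f)
  }
  back <- read_cohort(file.path(d1, "manifest.yaml"))
  expect_matrix_equal(back$omics$mirna$values, co$omics$mirna$values, 1e-9)
  expect_equal(back$survival$time, co$survival$time, tolerance = 1e-9)
})

test_that("replicate cohorts share generative structure but not samples", {
  cfg_a <- small_cohort_config(seed = 21, structure_seed = 500)
  cfg_b <- small_cohort_config(seed = 22, structure_seed = 500)
  a <- simulate_cohort(cfg_a)
  b <- simulate_cohort(cfg_b)
  expect_identical(a$motif_prior$weights, b$motif_prior$weights)
  expect_identical(a$truth$patterns$u, b$truth$patterns$u)
  expect_false(isTRUE(all.equal(a$truth$factors$scores, b$truth$factors$scores)))
})
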