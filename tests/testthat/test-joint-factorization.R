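make_filtered_blocks <- function(z, sizes, noise_sd = 0.05, seed = 1,
                                 threshold = 0.85, floor = 5) {
  blocks <- list()
  for (i in seq_along(sizes)) {
    blocks[[paste0("b", i)]] <- simulate_omics_block(
      z, sizes[i], seq_len(ncol(z$scores)), noise_sd = noise_sd,
      seed = seed + i, name = paste0("b", i))
  }
  lapply(blocks, filter_block, threshold = threshold, floor = floor)
}

test_that("a single-block factorization reduces to that block's PCA", {
  z <- simulate_latent_factors(40, 3, seed = 1)
  fb <- make_filtered_blocks(z, 30, noise_sd = 0.2, seed = 2)
  model <- fit_jdr(fb, K = 3)
  for (k in 1:3) {
    expect_gte(abs(cor(model$scores[, k], fb$b1$pca$scores[, k])), 1 - 1e-8)
  }
})

test_that("the default backend is deterministic and sample-order invariant", {
  z <- simulate_latent_factors(30, 2, seed = 3)
  fb <- make_filtered_blocks(z, c(20, 25), noise_sd = 0.3, seed = 4)
  m1 <- fit_jdr(fb, K = 2, seed = 13)
  m2 <- fit_jdr(fb, K = 2, seed = 13)
  expect_identical(m1$scores, m2$scores)

  perm <- sample(rownames(m1$scores))
  fb_perm <- lapply(fb, function(b) { b$pca$scores <- b$pca$scores[perm, ]; b })
  m3 <- fit_jdr(fb_perm, K = 2)
  expect_matrix_equal(m3$scores[rownames(m1$scores), ], m1$scores, 1e-8)
})

test_that("shared low-noise factors with graded effect sizes are recovered", {
  # equal effect sizes leave the factor basis rotationally unidentifiable
  # for any linear factorization; a graded (scree-like) spectrum makes the
  # factors separable
  z <- simulate_latent_factors(120, 3, seed = 5)
  fb <- list()
  for (i in 1:3) {
    fb[[paste0("b", i)]] <- filter_block(
      simulate_omics_block(z, c(120, 80, 100)[i], 1:3,
                           loading_scale = c(4, 2, 1), noise_sd = 0.05,
                           seed = 5 + i, name = paste0("b", i)),
      threshold = 0.85, floor = 10, scale = FALSE)
  }
  model <- fit_jdr(fb, K = 3)
  cors <- abs(cor(model$scores, z$scores))
  expect_true(all(apply(cors, 2, max) >= 0.95))
})

test_that("mismatched or rank-deficient inputs are rejected", {
  z <- simulate_latent_factors(20, 2, seed = 7)
  fb <- make_filtered_blocks(z, c(15, 15), noise_sd = 0.3, seed = 8)
  fb$b2$pca$scores <- fb$b2$pca$scores[-(1:2), ]
  expect_error(fit_jdr(fb, K = 2), "offending samples")

  fb2 <- make_filtered_blocks(z, 10, noise_sd = 0.3, seed = 9, floor = 2)
  expect_error(fit_jdr(fb2, K = 50), "rank")
})

test_that("variance explained matches direct residual computation", {
  z <- simulate_latent_factors(40, 2, seed = 10)
  # a noiseless rank-1 block built from one factor: that factor explains
  # everything, the other factor nothing
  b1 <- simulate_omics_block(z, 20, 1, noise_sd = 0, seed = 11, name = "b1")
  fb1 <- list(b1 = filter_block(b1, floor = 1, scale = FALSE))
  m1 <- fit_jdr(fb1, K = 1)
  expect_gte(m1$variance_explained["b1", 1], 1 - 1e-6)

  # direct Frobenius oracle on a random configuration
  fb3 <- make_filtered_blocks(z, c(12, 18), noise_sd = 0.4, seed = 13, floor = 3)
  m3 <- fit_jdr(fb3, K = 2)
  ve3 <- variance_explained(m3, fb3)
  for (m in 1:2) {
    s <- fb3[[m]]$pca$scores
    s <- sweep(s, 2, colMeans(s))
    for (k in 1:2) {
      res <- s - m3$scores[, k, drop = FALSE] %*% t(m3$block_weights[[m]][, k, drop = FALSE])
      expect_equal(ve3[m, k], 1 - sum(res^2) / sum(s^2), tolerance = 1e-10)
    }
  }
  # zeroing a factor's weights never increases its variance explained
  m0 <- m3
  m0$block_weights[[1]][, 1] <- 0
  ve0 <- variance_explained(m0, fb3)
  expect_lte(ve0[1, 1], ve3[1, 1] + 1e-12)
  expect_equal(ve0[1, 1], 0)
})

test_that("back-mapping equals a direct fit when all PCs are retained", {
  z <- simulate_latent_factors(30, 3, seed = 14)
  b1 <- simulate_omics_block(z, 12, 1:3, noise_sd = 0.2, seed = 15, name = "a")
  b2 <- simulate_omics_block(z, 9, 1:3, noise_sd = 0.2, seed = 16, name = "b")
  fb <- suppressWarnings(lapply(list(a = b1, b = b2), filter_block,
                                threshold = 1, floor = 12, scale = TRUE))
  model <- fit_jdr(fb, K = 3)
  mapped <- backmap_model(model, fb)
  direct <- fit_jdr(lapply(list(a = b1, b = b2),
                           function(b) scale(t(b$values))), K = 3)
  for (nm in c("a", "b")) for (k in 1:3) {
    d <- min(max(abs(mapped[[nm]][, k] - direct$block_weights[[nm]][, k])),
             max(abs(mapped[[nm]][, k] + direct$block_weights[[nm]][, k])))
    expect_lt(d, 1e-8)
  }

  # identity loadings pass the weights through unchanged
  w <- matrix(rnorm(12), 4, 3)
  expect_identical(backmap_weights(diag(4), w), w)
  expect_error(backmap_weights(diag(3), w), "inner dimensions")
})

test_that("truncated back-mapping preserves feature rankings", {
  z <- simulate_latent_factors(60, 3, seed = 17)
  b <- simulate_omics_block(z, 80, 1:3, noise_sd = 0.3, seed = 18, name = "a")
  full <- suppressWarnings(filter_block(b, threshold = 1, floor = 60))
  trunc <- filter_block(b, threshold = 0.85, floor = 3)
  m_full <- fit_jdr(list(a = full), K = 3)
  m_trunc <- fit_jdr(list(a = trunc), K = 3)
  w_full <- backmap_model(m_full, list(a = full))$a
  w_trunc <- backmap_model(m_trunc, list(a = trunc))$a
  # factors may come out in a different order; match by score correlation
  match_k <- apply(abs(cor(m_trunc$scores, m_full$scores)), 1, which.max)
  for (k in 1:3) {
    rc <- abs(cor(abs(w_trunc[, k]), abs(w_full[, match_k[k]]),
                  method = "spearman"))
    expect_gte(rc, 0.9)
  }
})

test_that("factor correlation is symmetric in the expected ways", {
  z <- simulate_latent_factors(50, 3, seed = 19)
  fb <- make_filtered_blocks(z, c(30, 30), noise_sd = 0.2, seed = 20)
  m <- fit_jdr(fb, K = 3)
  self <- factor_correlation(m, m)
  expect_equal(unname(diag(self)), rep(1, 3))

  flipped <- m
  flipped$scores <- -flipped$scores
  expect_equal(unname(diag(factor_correlation(m, flipped))), rep(1, 3))

  set.seed(21)
  za <- matrix(rnorm(200 * 3), 200, 3, dimnames = list(.ids <- sprintf("S%03d", 1:200), NULL))
  zb <- matrix(rnorm(200 * 3), 200, 3, dimnames = list(.ids, NULL))
  expect_lt(max(factor_correlation(za, zb)), 0.3)

  expect_error(factor_correlation(za[1:2, ], zb[1:2, ]), "3 shared")
})

test_that("factor models serialize to TSV + YAML", {
  z <- simulate_latent_factors(20, 2, seed = 22)
  fb <- make_filtered_blocks(z, 15, noise_sd = 0.3, seed = 23, floor = 3)
  m <- fit_jdr(fb, K = 2)
  d <- file.path(tempdir(), "fm_out")
  write_factor_model(m, d)
  meta <- yaml::read_yaml(file.path(d, "model.yaml"))
  expect_identical(meta$K, 2L)
  expect_true(file.exists(file.path(d, "factor_scores.tsv")))
})
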