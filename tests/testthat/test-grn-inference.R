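test_that("co-expression matches the pairwise Pearson formula", {
  set.seed(1)
  x <- matrix(rnorm(50), 5, 10, dimnames = list(paste0("g", 1:5), NULL))
  co <- compute_coexpression(x)
  for (i in 1:5) for (j in 1:5) {
    expect_equal(unclass(co)[i, j],
                 if (i == j) 1 else pearson_oracle(x[i, ], x[j, ]),
                 tolerance = 1e-12)
  }

  dup <- rbind(a = x[1, ], b = x[1, ], c = -x[1, ])
  co2 <- compute_coexpression(dup)
  expect_equal(unclass(co2)["a", "b"], 1)
  expect_equal(unclass(co2)["a", "c"], -1)

  bad <- rbind(x, flatgene = rep(2, 10))
  expect_error(compute_coexpression(bad), "flatgene")
  expect_error(compute_coexpression(x[, 1:2]), "3 samples")
})

# straight-line transcription of the message-passing update, scalar loops only
panda_one_step_oracle <- function(m, p, co, alpha) {
  zn <- function(a) (a - mean(a)) / sd(a)
  w <- zn(m); pp <- zn(p); cc <- zn(co)
  tani <- function(x, y) sum(x * y) / sqrt(sum(x^2) + sum(y^2) - abs(sum(x * y)))
  w_new <- w
  for (i in seq_len(nrow(w))) for (j in seq_len(ncol(w))) {
    r_ij <- tani(pp[i, ], w[, j])
    a_ij <- tani(w[i, ], cc[, j])
    w_new[i, j] <- (1 - alpha) * w[i, j] + alpha * (r_ij + a_ij) / 2
  }
  w_new
}

test_that("message-passing inference: degenerate cases and one-step oracle", {
  set.seed(2)
  m <- matrix(c(1, 0, 1, 1, 0, 1), 2, 3)
  p <- matrix(c(1, 0.5, 0.5, 1), 2, 2)
  expr <- matrix(rnorm(30), 3, 10, dimnames = list(paste0("G", 1:3), NULL))
  co <- compute_coexpression(expr)

  zn <- function(a) (a - mean(a)) / sd(a)
  g0 <- panda_aggregate(m, p, co, alpha = 0)
  expect_matrix_equal(g0$weights, zn(m))
  expect_true(g0$converged)
  expect_identical(g0$n_iterations, 1L)

  gm0 <- panda_aggregate(m, p, co, alpha = 0.1, max_iter = 0)
  expect_matrix_equal(gm0$weights, zn(m))
  expect_false(gm0$converged)

  g1 <- panda_aggregate(m, p, co, alpha = 0.1, max_iter = 1)
  expect_matrix_equal(g1$weights, panda_one_step_oracle(m, p, unclass(co), 0.1),
                      tol = 1e-10)
})

test_that("message passing is equivariant under node relabeling", {
  set.seed(3)
  pr <- simulate_priors(5, 12, motif_density = 0.4, ppi_density = 0.3, seed = 4)
  expr <- matrix(rnorm(12 * 15), 12, 15,
                 dimnames = list(colnames(pr$motif$weights), NULL))
  g <- panda_aggregate(pr$motif, pr$ppi, compute_coexpression(expr),
                       alpha = 0.1, max_iter = 5)
  pi_tf <- sample(5)
  pi_g <- sample(12)
  g_perm <- panda_aggregate(pr$motif$weights[pi_tf, pi_g],
                            pr$ppi$weights[pi_tf, pi_tf],
                            compute_coexpression(expr)[pi_g, pi_g],
                            alpha = 0.1, max_iter = 5)
  expect_matrix_equal(g_perm$weights, g$weights[pi_tf, pi_g], tol = 1e-10)
})

test_that("message passing converges on realistic inputs", {
  pr <- simulate_priors(10, 30, motif_density = 0.3, ppi_density = 0.2, seed = 5)
  set.seed(6)
  expr <- matrix(rnorm(30 * 40), 30, 40,
                 dimnames = list(colnames(pr$motif$weights), NULL))
  g <- panda_aggregate(pr$motif, pr$ppi, compute_coexpression(expr),
                       alpha = 0.1, tol = 1e-3, max_iter = 200)
  expect_true(g$converged)
  expect_true(all(is.finite(g$weights)))
  expect_error(panda_aggregate(pr$motif, pr$ppi, diag(5)), "genes")
})

test_that("single-sample interpolation recovers linear contributions exactly", {
  set.seed(7)
  x <- matrix(rnorm(6 * 10), 6, 10,
              dimnames = list(paste0("f", 1:6), paste0("s", 1:10)))
  contrib <- function(v) outer(v[1:2], v[3:6])
  nets <- lioness_networks(x, netfn_contribution(contrib))
  for (q in 1:10) {
    expect_matrix_equal(matrix(nets$weights[q, ], 2, 4), contrib(x[, q]),
                        tol = 1e-10)
  }
  # mean of single-sample networks equals the aggregate
  agg <- netfn_contribution(contrib)(x)
  expect_matrix_equal(matrix(colMeans(nets$weights), 2, 4), agg, tol = 1e-10)
})

test_that("interpolation arithmetic and degenerate inputs", {
  # constructed estimator: e(all) = 1 on both samples, 0 on any subset
  fn <- function(x) matrix(as.numeric(ncol(x) == 2), 1, 1)
  x2 <- matrix(rnorm(4), 2, 2, dimnames = list(NULL, c("a", "b")))
  nets <- lioness_networks(x2, fn)
  expect_equal(as.vector(nets$weights), c(2, 2))

  # identical samples: every leave-one-out aggregate equals the full one
  xid <- matrix(rep(1:4, 5), 4, 5, dimnames = list(paste0("f", 1:4), NULL))
  fnc <- netfn_contribution(function(v) outer(v[1:2], v[3:4]))
  nid <- lioness_networks(xid, fnc)
  agg <- fnc(xid)
  for (q in 1:5) expect_matrix_equal(matrix(nid$weights[q, ], 2, 2), agg)

  expect_error(lioness_networks(matrix(1:3, 3, 1), fn), "single sample")
})

test_that("degrees are row/column sums and conserve total edge weight", {
  w <- matrix(c(1, 3, 2, 4), 2, 2,
              dimnames = list(c("TF1", "TF2"), c("g1", "g2")))
  expect_equal(unname(indegree(w)), c(4, 6))
  expect_equal(unname(outdegree(w)), c(3, 7))
  expect_equal(sum(indegree(w)), sum(outdegree(w)))
  expect_equal(unname(indegree(matrix(0, 3, 4))), rep(0, 4))

  set.seed(8)
  ws <- matrix(rnorm(3 * 40), 3, 40)
  nets <- sample_network_set(ws, tf_ids = paste0("TF", 1:5),
                             gene_ids = paste0("g", 1:8))
  ind <- indegree(nets)
  outd <- outdegree(nets)
  for (q in 1:3) {
    wq <- matrix(ws[q, ], 5, 8)
    # brute-force per-column / per-row summation
    expect_equal(unname(ind$values[q, ]),
                 sapply(1:8, function(j) sum(wq[, j])))
    expect_equal(unname(outd$values[q, ]),
                 sapply(1:5, function(i) sum(wq[i, ])))
    expect_equal(sum(ind$values[q, ]), sum(wq))
  }
})

test_that("streamed degrees agree with the materialized network set", {
  set.seed(9)
  pr <- simulate_priors(6, 15, motif_density = 0.4, seed = 10)
  x <- matrix(rnorm(15 * 12), 15, 12,
              dimnames = list(colnames(pr$motif$weights), paste0("s", 1:12)))
  fn <- netfn_prior_attribution(pr$motif)
  full <- lioness_networks(x, fn)
  streamed <- lioness_degrees(x, fn)
  expect_matrix_equal(streamed$indegree$values, indegree(full)$values, 1e-10)
  expect_matrix_equal(streamed$outdegree$values, outdegree(full)$values, 1e-10)
})

test_that("motif-masked correlation estimator is usable for interpolation", {
  set.seed(10)
  pr <- simulate_priors(4, 10, motif_density = 0.5, seed = 11)
  ids <- c(rownames(pr$motif$weights), colnames(pr$motif$weights))
  x <- matrix(rnorm(length(ids) * 20), length(ids), 20,
              dimnames = list(ids, paste0("s", 1:20)))
  nets <- lioness_networks(x, netfn_masked_cor(pr$motif))
  expect_identical(dim(nets$weights), c(20L, 40L))
  expect_true(all(is.finite(nets$weights)))
  # unsupported edges stay exactly zero for every sample
  zero_edges <- as.vector(pr$motif$weights) == 0
  expect_true(all(nets$weights[, zero_edges] == 0))
})
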