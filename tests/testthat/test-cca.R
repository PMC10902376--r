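test_that("canonical correlation matches the grid-search oracle", {
  set.seed(14)
  for (i in 1:3) {
    X <- matrix(rnorm(60 * 2), 60, 2)
    Y <- 0.5 * X + matrix(rnorm(60 * 2), 60, 2)
    fit <- fit_cca(X, Y)
    expect_lt(abs(fit$r - cca_grid_oracle(X, Y)), 1e-3)
  }
})

test_that("CCA basics: perfect, null, and scaling conventions", {
  set.seed(15)
  x <- matrix(rnorm(50), 50, 1)
  fit <- fit_cca(x, x)                      # Y duplicates X
  expect_equal(fit$r, 1, tolerance = 1e-9)
  expect_equal(sum(fit$u^2), 1, tolerance = 1e-9)
  expect_equal(sum(fit$v^2), 1, tolerance = 1e-9)
  expect_equal(fit$u, drop(fit$X %*% fit$a), tolerance = 1e-12)
  # independent blocks at large n: r near zero
  Xn <- matrix(rnorm(10000 * 2), 10000, 2)
  Yn <- matrix(rnorm(10000 * 2), 10000, 2)
  expect_lt(fit_cca(Xn, Yn)$r, 0.05)
  # errors when within-block covariance cannot be inverted
  expect_error(fit_cca(matrix(rnorm(8), 4, 2), matrix(rnorm(12), 4, 3)),
               "ridge")
  expect_error(fit_cca(cbind(rnorm(30), 1), matrix(rnorm(30), 30, 1)),
               "ridge")
})

test_that("r is invariant under invertible within-block transforms", {
  set.seed(16)
  X <- matrix(rnorm(80 * 3), 80, 3)
  Y <- X[, 1:2] + matrix(rnorm(80 * 2), 80, 2)
  r0 <- fit_cca(X, Y)$r
  A <- matrix(rnorm(9), 3, 3); while (abs(det(A)) < 0.1) A <- matrix(rnorm(9), 3, 3)
  B <- matrix(rnorm(4), 2, 2); while (abs(det(B)) < 0.1) B <- matrix(rnorm(4), 2, 2)
  r1 <- fit_cca(X %*% A, Y %*% B)$r
  expect_lt(abs(r0 - r1), 1e-9)
  # optimality: r bounds any single-column correlation
  expect_gte(r0 + 1e-12, max(abs(stats::cor(X, Y))))
  # cross-check against the reference implementation in base R
  cc <- stats::cancor(scale(X, scale = FALSE), scale(Y, scale = FALSE))
  expect_equal(r0, cc$cor[1], tolerance = 1e-9)
})

test_that("permutation p-value respects its bounds and detects signal", {
  set.seed(17)
  x <- matrix(rnorm(40), 40, 1)
  fit <- fit_cca(x, x)
  # nothing can beat perfect correlation (generically)
  expect_equal(cca_pvalue(fit, n_perm = 199, seed = 2), 1 / 200)
  # independent data: p well inside (0, 1]
  Xn <- matrix(rnorm(60 * 2), 60, 2); Yn <- matrix(rnorm(60 * 2), 60, 2)
  p0 <- cca_pvalue(fit_cca(Xn, Yn), n_perm = 199, seed = 2)
  expect_gte(p0, 1 / 200)
  expect_lte(p0, 1)
  expect_warning(cca_pvalue(fit, n_perm = 50, seed = 1), "coarse")
})

test_that("Bartlett and permutation p-values agree on planted correlation", {
  set.seed(18)
  n <- 250
  z <- rnorm(n)
  X <- cbind(z + rnorm(n, sd = 1.2), rnorm(n))
  Y <- cbind(z + rnorm(n, sd = 1.2), rnorm(n))
  fit <- fit_cca(X, Y)
  p_perm <- cca_pvalue(fit, "permutation", n_perm = 499, seed = 3)
  p_bart <- cca_pvalue(fit, "bartlett")
  expect_lt(p_perm, 0.01)
  expect_lt(p_bart, 0.01)
})

test_that("kNN latent prediction votes, tie-breaks and scores correctly", {
  train <- rbind(matrix(rnorm(60, 0, 0.3), 30, 2),
                 matrix(rnorm(60, 4, 0.3), 30, 2),
                 cbind(rnorm(30, 0, 0.3), rnorm(30, 4, 0.3)))
  labs <- rep(1:3, each = 30)
  # a test point identical to a training point with k = 1
  out1 <- knn_latent_predict(train, labs, train[c(1, 31, 61), , drop = FALSE],
                             k = 1)
  expect_equal(out1$predicted, c(1, 2, 3))
  set.seed(19)
  test <- rbind(matrix(rnorm(40, 0, 0.3), 20, 2),
                matrix(rnorm(40, 4, 0.3), 20, 2),
                cbind(rnorm(20, 0, 0.3), rnorm(20, 4, 0.3)))
  out <- knn_latent_predict(train, labs, test, k = 13,
                            test_labels = rep(1:3, each = 20))
  expect_gte(out$accuracy, 0.95)
  expect_equal(dim(out$confusion), c(3L, 3L))
  expect_error(knn_latent_predict(train, labs, test, k = 1000), "exceeds")
})

test_that("feature-gene correlations flag constants and find planted links", {
  set.seed(20)
  n <- 300
  gene <- rbinom(n, 1, 0.4)
  X <- cbind(f1 = rnorm(n) + 1.2 * gene, f2 = rnorm(n))
  Y <- cbind(g1 = gene, g2 = rep(0L, n))
  out <- feature_gene_correlation(X, Y)
  planted <- out[out$feature == "f1" & out$gene == "g1", ]
  expect_gt(planted$r, 0)
  expect_true(planted$significant)
  expect_equal(out$flag[out$gene == "g2"], rep("constant", 2))
  expect_true(all(is.na(out$r[out$gene == "g2"])))
  # a feature equal to the gene indicator correlates perfectly
  out2 <- feature_gene_correlation(cbind(f = gene), cbind(g = gene))
  expect_equal(out2$r, 1, tolerance = 1e-12)
  # per-subtype strata appear when labels are given
  out3 <- feature_gene_correlation(X, Y, labels = rep(1:2, each = n / 2))
  expect_setequal(unique(out3$stratum), c("all", "subtype_1", "subtype_2"))
})
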