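test_that("anchor selection samples common subjects reproducibly", {
  co <- generate_cohort(synthetic_config(n_subjects = 200, seed = 3))
  ds <- co$dataset
  common <- ds$subject_ids[ds$has_imaging & ds$has_genomic]
  a1 <- select_anchors(ds, 20, seed = 5)
  a2 <- select_anchors(ds, 20, seed = 5)
  expect_identical(a1, a2)
  expect_true(all(a1$anchor_subject_ids %in% common))
  # K = all common subjects returns exactly them
  a_all <- select_anchors(ds, length(common), seed = 1)
  expect_setequal(a_all$anchor_subject_ids, common)
  expect_error(select_anchors(ds, length(common) + 1), "exceeds")
  a_km <- select_anchors(ds, 10, seed = 1, strategy = "kmeans-medoid")
  expect_length(a_km$anchor_subject_ids, 10)
  # no common subjects: method inapplicable
  ds2 <- ds; ds2$has_genomic <- !ds2$has_imaging
  ds2$genomic[ds2$has_imaging, ] <- NA_integer_
  expect_error(select_anchors(ds2, 5), "both modalities")
})

test_that("anchor similarity matches direct kernel evaluation in 1-D", {
  V <- matrix(c(0, 1, 3), 3, 1)
  U <- matrix(c(0, 2), 2, 1)
  as_ <- anchor_similarity(V, U, s = 2)
  d <- abs(outer(drop(V), drop(U), "-"))
  sigma <- mean(apply(d, 1, function(r) sort(r)[2]))  # default bandwidth rule
  expect_equal(as_$bandwidth, sigma)
  Zexp <- exp(-d^2 / (2 * sigma^2))
  Zexp <- Zexp / rowSums(Zexp)
  expect_equal(unname(as_$Z), unname(Zexp), tolerance = 1e-12)
  # rows sum to 1 with s nonzeros
  expect_equal(rowSums(as_$Z), rep(1, 3), tolerance = 1e-9)
})

test_that("a subject on an anchor gets an indicator row at s = 1", {
  V <- matrix(c(0, 0.5), 2, 1)
  U <- matrix(c(0, 2), 2, 1)
  as_ <- anchor_similarity(V, U, s = 1)
  expect_equal(unname(as_$Z[1, ]), c(1, 0))
  # equidistant subject with s = 2 gets equal weights
  V2 <- matrix(1, 1, 1)
  as2 <- anchor_similarity(V2, U, s = 2)
  expect_equal(unname(as2$Z[1, ]), c(0.5, 0.5))
  # coincident degenerate cloud: zero bandwidth rejected
  expect_error(anchor_similarity(matrix(0, 3, 1), matrix(0, 2, 1), s = 2),
               "bandwidth")
})

test_that("fusion copies single-view rows and averages shared ones", {
  ds <- partial_mm_dataset(
    c("a", "b", "c"),
    imaging = rbind(c(1, 1), c(2, 2), c(NA, NA)),
    genomic = rbind(c(0L, 1L), NA, c(1L, 1L)),
    has_imaging = c(TRUE, TRUE, FALSE),
    has_genomic = c(TRUE, FALSE, TRUE),
    cohort_split = rep("discovery", 3))
  Zi <- rbind(c(1, 0), c(0.3, 0.7))        # imaging-present: a, b
  Zg <- rbind(c(0, 1), c(0.5, 0.5))        # genomic-present: a, c
  fz <- fuse_anchor_graphs(Zi, Zg, ds)
  expect_equal(unname(fz["a", ]), c(0.5, 0.5))   # (1,0) and (0,1) averaged
  expect_equal(unname(fz["b", ]), c(0.3, 0.7))   # imaging-only copy
  expect_equal(unname(fz["c", ]), c(0.5, 0.5))   # genomic-only copy
  expect_equal(unname(rowSums(fz)), rep(1, 3), tolerance = 1e-12)
})

test_that("two-step similarity matches the double-sum formula", {
  Z <- rbind(c(0.7, 0.3), c(0.4, 0.6), c(1, 0))
  S <- two_step_similarity(Z)$S
  expect_equal(S, two_step_oracle(Z), tolerance = 1e-12)
  # identity Z: every subject its own anchor
  expect_equal(two_step_similarity(diag(4))$S, diag(4))
  # one shared anchor: complete mixing
  ones <- matrix(1, 5, 1)
  expect_equal(two_step_similarity(ones)$S, matrix(1 / 5, 5, 5))
  expect_warning(two_step_similarity(cbind(diag(3), 0)), "empty anchor")
})

test_that("similarity laws hold on random row-stochastic inputs", {
  set.seed(21)
  for (i in 1:20) {
    Z <- random_row_stochastic(sample(10:40, 1), sample(3:8, 1))
    S <- two_step_similarity(Z)$S
    expect_lt(max(abs(S - t(S))), 1e-9)
    expect_lt(max(abs(rowSums(S) - 1)), 1e-9)
    expect_gt(min(eigen(S, symmetric = TRUE, only.values = TRUE)$values),
              -1e-9)
  }
})

test_that("spectral clustering recovers block structure and is equivariant", {
  S <- matrix(0, 6, 6)
  S[1:3, 1:3] <- 1 / 3; S[4:6, 4:6] <- 1 / 3
  lab <- spectral_cluster(S, 2, seed = 1)
  expect_equal(lab[1:3], rep(lab[1], 3))
  expect_equal(lab[4:6], rep(lab[4], 3))
  expect_false(lab[1] == lab[4])
  # permutation equivariance (up to the size-ordered relabeling convention)
  set.seed(2)
  X <- rbind(matrix(rnorm(40, 0), 20, 2), matrix(rnorm(40, 6), 20, 2))
  Z <- anchor_similarity(X, X[c(1:5, 21:25), ], s = 3)$Z
  S2 <- two_step_similarity(Z)$S
  perm <- sample(40)
  lab_a <- spectral_cluster(S2, 2, seed = 7)
  lab_b <- spectral_cluster(S2[perm, perm], 2, seed = 7)
  expect_equal(adjusted_rand_index(lab_a[perm], lab_b), 1)
  expect_error(spectral_cluster(S, 9), "exceeds")
})

test_that("gap statistic finds one blob and three blobs", {
  # 6-d geometry, matching the dimensionality regime the method is used in
  set.seed(4)
  one <- matrix(rnorm(100 * 6), 100, 6)
  Z1 <- anchor_similarity(one, one[1:20, ], s = 10)$Z
  expect_equal(gap_statistic_k(Z1, 1:4, B = 20, seed = 3)$k, 1)
  set.seed(1)
  mu <- rbind(rep(0, 6), rep(2, 6), rep(c(0, 2), 3))
  three <- do.call(rbind, lapply(1:3, function(c_)
    matrix(rnorm(50 * 6, mean = rep(mu[c_, ], each = 50)), 50, 6)))
  Z3 <- anchor_similarity(three, three[seq(1, 150, by = 5), ], s = 10)$Z
  expect_equal(gap_statistic_k(Z3, 1:6, B = 20, seed = 3)$k, 3)
  expect_error(gap_statistic_k(Z3, 1:6, B = 5), "at least 10")
})

test_that("run_apmc on complete data equals the manually composed chain", {
  co <- small_cohort(n = 150, seed = 6)
  rd <- reduce_dataset(co$dataset, n_features = 6)
  cfg <- apmc_config(k = 3, seed = 9)
  asg <- run_apmc(rd$dataset, cfg)
  common <- sum(rd$dataset$has_imaging & rd$dataset$has_genomic)
  anch <- select_anchors(rd$dataset, max(2L, min(50L, common %/% 2L)),
                         seed = 9)
  Zi <- anchor_similarity(rd$dataset$imaging, anch$u_imaging)
  Zg <- anchor_similarity(rd$dataset$genomic, anch$u_genomic)
  fz <- fuse_anchor_graphs(Zi, Zg, rd$dataset)
  lab <- spectral_cluster(two_step_similarity(fz), 3, seed = 9)
  expect_equal(unname(asg$labels), as.vector(lab))
})

test_that("strong planted structure is recovered identically across seeds", {
  co <- generate_cohort(synthetic_config(
    n_subjects = 300, subtype_separation = 3, frac_both = 1,
    frac_imaging_only = 0, frac_genomic_only = 0, seed = 8))
  a1 <- fixture_chain(co, k = 3, seed = 101)
  a2 <- fixture_chain(co, k = 3, seed = 202)
  expect_equal(adjusted_rand_index(a1$labels, a2$labels), 1)
  expect_gt(adjusted_rand_index(a1$labels, co$truth$subtype_labels), 0.95)
})
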