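test_that("config validation rejects inconsistent settings", {
  expect_error(synthetic_config(frac_both = 0.5, frac_imaging_only = 0.3,
                                frac_genomic_only = 0.3), "sum to 1")
  expect_error(synthetic_config(n_subjects = 2, n_subtypes = 3),
               "at least as many subjects")
  expect_error(synthetic_config(n_imaging_features = 10,
                                n_informative_features = 12),
               "exceeds")
  expect_error(synthetic_config(pathway_map = list(BAD = "NOSUCHGENE")),
               "NOSUCHGENE")
  expect_error(synthetic_config(subtype_hazards = c(1, 0.7)),
               "one multiplier per subtype")
})

test_that("identical config and seed give bit-identical cohorts", {
  a <- generate_cohort(synthetic_config(n_subjects = 150, seed = 3))
  b <- generate_cohort(synthetic_config(n_subjects = 150, seed = 3))
  expect_identical(a, b)
  c <- generate_cohort(synthetic_config(n_subjects = 150, seed = 4))
  expect_false(identical(a$dataset$imaging, c$dataset$imaging))
})

test_that("degenerate fractions give complete data; all subjects observed", {
  co <- small_cohort(n = 80, seed = 2)
  expect_true(all(co$dataset$has_imaging))
  expect_true(all(co$dataset$has_genomic))
  co2 <- generate_cohort(synthetic_config(n_subjects = 400, seed = 2))
  expect_true(all(co2$dataset$has_imaging | co2$dataset$has_genomic))
  # masks consistent with stored rows
  expect_false(anyNA(co2$dataset$imaging[co2$dataset$has_imaging, ]))
  expect_true(all(is.na(co2$dataset$imaging[!co2$dataset$has_imaging, ])))
})

test_that("availability fractions converge to the configured proportions", {
  co <- generate_cohort(synthetic_config(n_subjects = 5000, seed = 9))
  both <- mean(co$dataset$has_imaging & co$dataset$has_genomic)
  img <- mean(co$dataset$has_imaging & !co$dataset$has_genomic)
  gen <- mean(!co$dataset$has_imaging & co$dataset$has_genomic)
  expect_lt(abs(both - 0.46), 0.02)
  expect_lt(abs(img - 0.33), 0.02)
  expect_lt(abs(gen - 0.21), 0.02)
})

test_that("survival generation reflects the planted hazard ordering", {
  co <- generate_cohort(synthetic_config(n_subjects = 5000, seed = 5))
  tr <- unname(co$truth$subtype_labels)
  med <- vapply(1:3, function(s) {
    fit <- survival::survfit(survival::Surv(
      co$clinical$os_time[tr == s], co$clinical$event[tr == s]) ~ 1)
    unname(summary(fit)$table["median"])
  }, numeric(1))
  # multipliers 1.0 > 0.725 > 0.586 => medians increase with subtype index
  expect_true(med[1] < med[2] && med[2] < med[3])
  expect_lt(abs(mean(co$clinical$event == 0) - 0.30), 0.03)
})

test_that("planted co-occurring pair shows empirical odds ratio > 1", {
  co <- generate_cohort(synthetic_config(n_subjects = 2000, seed = 7))
  tr <- unname(co$truth$subtype_labels)
  gen <- co$dataset$genomic[co$dataset$has_genomic, ]
  lab <- tr[co$dataset$has_genomic]
  for (s in 1:3) {
    M <- gen[lab == s, ]
    a <- sum(M[, "TP53"] & M[, "RB1"]); b <- sum(M[, "TP53"] & !M[, "RB1"])
    c_ <- sum(!M[, "TP53"] & M[, "RB1"]); d <- sum(!M[, "TP53"] & !M[, "RB1"])
    expect_gt((a * d) / (b * c_), 1)
  }
})

test_that("null config carries no recoverable subtype signal", {
  cfg <- synthetic_config(n_subjects = 200, n_imaging_features = 30,
                          n_informative_features = 6,
                          subtype_separation = 0, mutation_boost = 1,
                          cooccurrence_pairs = list(),
                          subtype_hazards = c(1, 1, 1), seed = 13)
  co <- generate_cohort(cfg)
  asg <- fixture_chain(co, k = 3, n_features = 6)
  expect_lt(abs(adjusted_rand_index(asg$labels, co$truth$subtype_labels)),
            0.15)
})

test_that("mask_availability preserves data and truth while masking rows", {
  co <- small_cohort(n = 300, seed = 4)
  masked <- mask_availability(co$dataset, seed = 21)
  expect_true(all(masked$has_imaging | masked$has_genomic))
  pres <- masked$has_imaging
  expect_identical(masked$imaging[pres, ], co$dataset$imaging[pres, ])
  expect_lt(abs(mean(masked$has_imaging & masked$has_genomic) - 0.46), 0.1)
})

test_that("pathway labels follow the OR rule over member genes", {
  genes <- gbm_genes()
  g <- matrix(0L, 3, length(genes), dimnames = list(NULL, genes))
  g[1, "RB1"] <- 1L                      # RB1 pathway via RB1 alone
  g[3, c("PTEN", "EGFR")] <- 1L          # PI3K and RTK simultaneously
  pw <- derive_pathway_labels(g)
  expect_identical(colnames(pw), c("RB1", "P53", "MAPK", "PI3K", "RTK"))
  expect_equal(unname(pw[1, ]), c(1L, 0L, 0L, 0L, 0L))
  expect_equal(unname(pw[2, ]), rep(0L, 5))     # all-zero row stays zero
  expect_equal(unname(pw[3, ]), c(0L, 0L, 0L, 1L, 1L))
  expect_error(derive_pathway_labels(g[, setdiff(genes, "CDKN2A")]),
               "CDKN2A")
})

test_that("dataset constructor enforces its invariants", {
  img <- matrix(rnorm(4), 2, 2); gen <- matrix(c(0L, 1L, 1L, 0L), 2, 2)
  expect_error(partial_mm_dataset(c("a", "b"), img, gen,
                                  c(FALSE, TRUE), c(FALSE, TRUE), c("d", "d")),
               "neither modality")
  gen_bad <- matrix(c(0.5, 1, 0, 1), 2, 2)
  expect_error(partial_mm_dataset(c("a", "b"), img, gen_bad,
                                  c(TRUE, TRUE), c(TRUE, TRUE), c("d", "d")),
               "binary")
})
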