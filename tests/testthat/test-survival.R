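test_that("KM without censoring equals the empirical survival function", {
  cl <- data.frame(os_time = c(1:5, 1:5), event = 1,
                   stringsAsFactors = FALSE)
  labs <- rep(1:2, each = 5)
  km <- km_logrank(cl, labs)
  g1 <- km$curves[km$curves$group == "1", ]
  expect_equal(g1$surv, seq(0.8, 0, by = -0.2), tolerance = 1e-12)
  # identical groups: no separation
  expect_lt(km$logrank_chisq, 1e-10)
  expect_gt(km$p_value, 0.999)
})

test_that("log-rank statistic matches the hand-computed toy", {
  # group A: deaths at 1,2,3,4; group B: times 1,2,3,4, events at 2 and 4.
  # Observed-minus-expected arithmetic done by hand:
  #  t=1: riskA 4/8, d=1 -> E_A 0.5,  V 0.25
  #  t=2: riskA 3/6, d=2 -> E_A 1.0,  V 0.4
  #  t=3: riskA 2/4, d=1 -> E_A 0.5,  V 0.25
  #  t=4: riskA 1/2, d=2 -> E_A 1.0,  V 0
  # O_A = 4, E_A = 3, V = 0.9 -> chi-sq = 1/0.9
  cl <- data.frame(os_time = c(1, 2, 3, 4, 1, 2, 3, 4),
                   event = c(1, 1, 1, 1, 0, 1, 0, 1))
  labs <- rep(c("A", "B"), each = 4)
  km <- km_logrank(cl, labs)
  expect_equal(km$logrank_chisq, 1 / 0.9, tolerance = 1e-10)
  expect_equal(km$df, 1L)
  expect_equal(km$p_value, stats::pchisq(1 / 0.9, 1, lower.tail = FALSE))
})

test_that("Cox recovers planted subtype hazards and a null covariate", {
  co <- generate_cohort(synthetic_config(n_subjects = 2000, frac_both = 1,
        frac_imaging_only = 0, frac_genomic_only = 0, seed = 6))
  tr <- unname(co$truth$subtype_labels)
  cx <- cox_fit(co$clinical, labels = tr, covariates = c("subtype", "sex"))
  uni <- cx$univariate
  hr2 <- uni$hazard_ratio[uni$term == "subtypeSubtype 2"]
  hr3 <- uni$hazard_ratio[uni$term == "subtypeSubtype 3"]
  expect_lt(abs(hr2 - 0.725), 0.1)
  expect_lt(abs(hr3 - 0.586), 0.1)
  # sex was generated independently of survival
  sex <- uni[uni$term == "sexFemale", ]
  expect_gt(sex$p_value, 0.05)
  expect_lt(abs(sex$hazard_ratio - 1), 0.1)
  # screen: subtype admitted, sex not
  expect_true("subtype" %in% cx$admitted)
  expect_false("sex" %in% cx$admitted)
  # CI brackets the point estimate
  expect_true(all(uni$ci_low <= uni$hazard_ratio + 1e-12 &
                    uni$hazard_ratio <= uni$ci_high + 1e-12))
})

test_that("pairwise subtype HRs use the earlier subtype as reference", {
  co <- generate_cohort(synthetic_config(n_subjects = 1500, frac_both = 1,
        frac_imaging_only = 0, frac_genomic_only = 0, seed = 6))
  tr <- unname(co$truth$subtype_labels)
  ph <- pairwise_subtype_hr(co$clinical, tr)
  expect_equal(nrow(ph), 3L)
  hr13 <- ph$hazard_ratio[ph$reference == 1 & ph$comparison == 3]
  expect_lt(abs(hr13 - 0.586), 0.12)
  expect_true(all(ph$ci_low < ph$hazard_ratio & ph$hazard_ratio < ph$ci_high))
})

test_that("risk ordering renames the worst-survival cluster to subtype 1", {
  co <- generate_cohort(synthetic_config(n_subjects = 1000, frac_both = 1,
        frac_imaging_only = 0, frac_genomic_only = 0, seed = 7))
  tr <- unname(co$truth$subtype_labels)
  scrambled <- c(2L, 3L, 1L)[tr]     # permute labels arbitrarily
  fixed <- order_subtypes_by_risk(co$clinical, scrambled)
  km <- km_logrank(co$clinical, fixed)
  med <- km$medians[order(names(km$medians))]
  expect_true(med["1"] <= med["2"] && med["2"] <= med["3"])
  expect_equal(adjusted_rand_index(fixed, tr), 1)  # pure relabeling
})

test_that("subtype comparison tests behave at the null and at separation", {
  set.seed(8)
  labs <- rep(1:3, each = 60)
  df <- data.frame(
    noise = rnorm(180),
    perfect = labs,                      # numeric equal to the label
    cat_perfect = factor(letters[labs]),
    constant = rep(1, 180))
  out <- subtype_feature_tests(df, labs)
  expect_gt(out$p_value[out$variable == "noise"], 0.05)
  expect_lt(out$p_value[out$variable == "perfect"], 1e-10)
  expect_lt(out$p_value[out$variable == "cat_perfect"], 1e-10)
  expect_equal(out$p_value[out$variable == "constant"], 1)
  expect_equal(out$flag[out$variable == "constant"], "constant")
  expect_equal(out$test[out$variable == "noise"], "kruskal-wallis")
  expect_equal(out$test[out$variable == "cat_perfect"], "fisher")
})

test_that("Fisher p for a 2x2 table matches exhaustive enumeration", {
  # table (5,1 / 1,5)
  p_pkg <- stats::fisher.test(matrix(c(5, 1, 1, 5), 2))$p.value
  expect_equal(p_pkg, fisher_oracle(5, 1, 1, 5), tolerance = 1e-12)
})

test_that("empty groups are dropped and degenerate inputs rejected", {
  cl <- data.frame(os_time = c(1, 2, 3, 4), event = c(1, 1, 1, 0))
  expect_error(km_logrank(cl, rep(1, 4)), "at least 2")
  expect_warning(km_logrank(cl, factor(c(1, 1, 2, 2), levels = 1:3)),
                 "empty")
})
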