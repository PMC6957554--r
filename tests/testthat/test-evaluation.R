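test_that("rank-based AUC matches the concordant-pair oracle", {
  expect_equal(roc_auc(c(0.1, 0.9), c(FALSE, TRUE)), 1)
  expect_equal(roc_auc(rep(0.3, 10), rep(c(TRUE, FALSE), 5)), 0.5)
  set.seed(101)
  s <- sample(round(rnorm(200), 1))  # rounded scores force ties
  l <- runif(200) < 0.4
  pairs <- 0
  for (i in which(l)) for (j in which(!l)) {
    pairs <- pairs + (s[i] > s[j]) + 0.5 * (s[i] == s[j])
  }
  oracle <- pairs / (sum(l) * sum(!l))
  expect_equal(roc_auc(s, l), oracle, tolerance = 1e-12)
  # complement identity holds exactly under midranks
  expect_identical(roc_auc(s, l) + roc_auc(-s, l), 1)
  expect_error(roc_auc(1:5, rep(TRUE, 5)), "both classes")
})

test_that("region scores are masked means over each ROI", {
  vals <- matrix(0.5, 12, 12)
  roi <- matrix(0L, 12, 12); roi[3:5, 3:5] <- 1L; roi[8:10, 8:10] <- 2L
  rs <- region_scores(param_map("score", vals), roi)
  expect_equal(rs$mean_score, c(0.5, 0.5))
  # half +1 / half -1 averages to zero
  v2 <- vals; v2[8:10, 8:9] <- 1; v2[8:10, 10] <- -2
  rs2 <- region_scores(param_map("score", v2), roi)
  expect_equal(rs2$mean_score[rs2$label == "malignant"], 0)
  # seeded map equals the brute-force masked mean; invalid pixels excluded
  set.seed(33)
  v3 <- matrix(rnorm(144), 12, 12); v3[4, 4] <- NA
  m3 <- param_map("score", v3)
  rs3 <- region_scores(m3, roi)
  ben <- v3[roi == 1L]
  expect_equal(rs3$mean_score[rs3$label == "benign"],
               mean(ben, na.rm = TRUE), tolerance = 1e-12)
  # an ROI with no valid pixels is flagged
  v4 <- v3; v4[roi == 2L] <- NA
  rs4 <- region_scores(param_map("score", v4), roi)
  expect_true(rs4$flagged[rs4$label == "malignant"])
})

test_that("the rank-sum test is exact for small samples and calibrated", {
  # fully separated samples of 3: two-sided exact p = 2/20
  w <- wilcoxon_rank_sum(c(1, 2, 3), c(4, 5, 6))
  expect_true(w$U %in% c(0, 9))
  expect_equal(w$p, 0.1, tolerance = 1e-12)
  expect_equal(w$method, "exact enumeration")
  # identical samples are maximally non-significant
  expect_equal(wilcoxon_rank_sum(c(1, 2, 3), c(1, 2, 3))$p, 1,
               tolerance = 1e-9)
  # the large-sample approximation tracks the exact enumeration at n = 12
  set.seed(55)
  for (i in 1:20) {
    x <- rnorm(6); y <- rnorm(6, 0.5)
    pe <- wilcoxon_rank_sum(x, y)$p
    pa <- wilcoxon_rank_sum(x, y, exact_max = 0)$p
    expect_lt(abs(pe - pa), 0.01)
  }
  expect_error(wilcoxon_rank_sum(numeric(0), 1:3), "non-empty")
})

test_that("the rank-sum type-I error rate is near nominal", {
  set.seed(2024)
  hits <- replicate(1000, {
    wilcoxon_rank_sum(rnorm(10), rnorm(10))$significant
  })
  expect_gte(mean(hits), 0.03)
  expect_lte(mean(hits), 0.07)
})

test_that("the feature correlation matrix is a valid Pearson matrix", {
  set.seed(71)
  tab <- random_feature_table(n = 1000, seed = 71, driver = NULL)
  fc <- feature_correlation_matrix(tab)
  expect_identical(fc$correlation, t(fc$correlation))
  expect_true(all(diag(fc$correlation) == 1))
  # independent columns: small correlations, mostly non-significant
  off <- fc$correlation[upper.tri(fc$correlation)]
  expect_lt(max(abs(off)), 0.15)
  expect_gt(mean(fc$not_significant[upper.tri(fc$correlation)]), 0.80)
  # a duplicated feature shows as off-diagonal 1
  df <- as.data.frame(tab); df$v <- df$Pe
  fc2 <- feature_correlation_matrix(feature_table(df))
  expect_equal(fc2$correlation["Pe", "v"], 1)
  # zero-variance columns are flagged undefined
  df$G <- 0
  fc3 <- feature_correlation_matrix(feature_table(df))
  expect_true(all(is.na(fc3$correlation["G", ])))
})

test_that("leave-one-patient-out folds never contain their test patient", {
  tab <- random_feature_table(n = 700, n_patients = 10, seed = 91)
  cv <- lopo_crossval(tab, run_config(n_trees = 40), seed = 6)
  expect_length(cv$folds, 10)
  for (pat in names(cv$folds))
    expect_false(pat %in% cv$folds[[pat]])
  expect_true(all(abs(cv$pixel$score) <= 1, na.rm = TRUE))
  expect_lt(length(setdiff(unique(cv$pixel$patient_id), names(cv$folds))), 1)
  # fewer than 8 patients is refused
  expect_error(lopo_crossval(random_feature_table(n = 300, n_patients = 7),
                             run_config(n_trees = 5), 1),
               "8 patients")
})

test_that("single-parameter forest mode runs on a reduced manifest", {
  tab <- random_feature_table(n = 600, n_patients = 9, seed = 17,
                              driver = "v")
  sub <- single_feature_table(tab, "v")
  expect_identical(ft_manifest(sub), paste0("v", c("", ".rel", ".ent1",
                                                   ".ent2", ".ent3",
                                                   ".var2")))
  cv <- lopo_crossval(sub, run_config(n_trees = 40), seed = 2)
  # the driving feature alone supports good held-out discrimination
  expect_gt(cv$auc$mp_pixel, 0.8)
  expect_identical(names(cv$auc$feature_pixel), "v")
})

test_that("null features give chance-level held-out performance", {
  cfg <- run_config(n_trees = 60)
  aucs <- vapply(1:3, function(s) {
    tab <- random_feature_table(n = 900, n_patients = 9, seed = 300 + s,
                                driver = NULL)
    lopo_crossval(tab, cfg, seed = s)$auc$mp_pixel
  }, 0)
  expect_true(all(aucs >= 0.40 & aucs <= 0.60))
})
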