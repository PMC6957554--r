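test_that("training is reproducible and separates a separable fixture", {
  tab <- random_feature_table(seed = 42)
  cfg <- run_config(n_trees = 200)
  m1 <- train_zonal_forest(tab, cfg, seed = 5)
  m2 <- train_zonal_forest(tab, cfg, seed = 5)
  s1 <- score_pixels(m1, tab)
  expect_identical(s1, score_pixels(m2, tab))
  expect_true(all(s1 >= -1 & s1 <= 1))
  # label = sign(Pe): training-set ROC-AUC is essentially perfect
  expect_gte(roc_auc(s1, tab$label == "malignant"), 0.99)
  # a different seed gives a different ensemble
  m3 <- train_zonal_forest(tab, cfg, seed = 6)
  expect_false(identical(s1, score_pixels(m3, tab)))
})

test_that("training preconditions are enforced", {
  tab <- random_feature_table(n = 300, n_patients = 6)
  expect_error(train_zonal_forest(tab, run_config(n_trees = 5), 1),
               "at least 7 patients")
  # a single-class stratum is refused, naming the stratum
  tab2 <- random_feature_table(n = 400, n_patients = 10)
  df <- as.data.frame(tab2)
  df$label[df$zone == "TZ"] <- "benign"
  expect_error(train_zonal_forest(feature_table(df),
                                  run_config(n_trees = 5), 1),
               "TZ")
})

test_that("every tree excludes its six discarded patients from its bootstrap", {
  tab <- random_feature_table(seed = 1)
  m <- train_zonal_forest(tab, run_config(n_trees = 150), seed = 9)
  for (z in c("PZ", "TZ")) {
    st <- m$strata[[z]]
    expect_length(st$trees, 150)
    for (b in seq_along(st$trees)) {
      expect_length(st$discarded[[b]], 6)
      expect_false(any(st$patient_ids[st$boot_rows[[b]]] %in%
                         st$discarded[[b]]))
    }
  }
})

test_that("the score is the per-tree vote tally over the zone's stratum", {
  tab <- random_feature_table(n = 600, seed = 7)
  cfg <- run_config(n_trees = 60)
  m <- train_zonal_forest(tab, cfg, seed = 3)
  s <- score_pixels(m, tab)
  X <- as.matrix(as.data.frame(tab)[, ft_manifest(tab)])
  zone <- as.data.frame(tab)$zone
  oracle <- vapply(seq_len(nrow(X)), function(i) {
    trees <- m$strata[[zone[i]]]$trees
    votes <- vapply(trees, function(tr)
      mpus:::.predict_tree_cpp(tr, X[i, , drop = FALSE]), integer(1))
    (sum(votes == 1) - sum(votes == 0)) / cfg$n_trees
  }, 0)
  expect_equal(s, oracle, tolerance = 1e-12)
  # rows with unknown zone or incomplete features score NA
  Xna <- X; Xna[1, 3] <- NA
  expect_true(is.na(score_pixels(m, Xna, zone)[1]))
})

test_that("retraining with swapped labels negates the score", {
  tab <- random_feature_table(seed = 4)
  cfg <- run_config(n_trees = 120)
  m <- train_zonal_forest(tab, cfg, seed = 8)
  df <- as.data.frame(tab)
  df$label <- ifelse(df$label == "malignant", "benign", "malignant")
  m2 <- train_zonal_forest(feature_table(df), cfg, seed = 8)
  expect_equal(score_pixels(m, tab), -score_pixels(m2, tab),
               tolerance = 1e-12)
})

test_that("the forced zonal split equals two per-stratum forests", {
  tab <- random_feature_table(n = 800, seed = 15)
  m <- train_zonal_forest(tab, run_config(n_trees = 80), seed = 2)
  chk <- zonal_equivalence_check(m, tab)
  expect_true(chk$equivalent)
  expect_true(is.na(chk$first_mismatch))
  # a PZ-only probe consults no TZ trees
  df <- as.data.frame(tab)
  probe <- feature_table(df[df$zone == "PZ", ])
  chk2 <- zonal_equivalence_check(m, tab, probe)
  expect_equal(unname(chk2$trees_used["TZ"]), 0)
  # flipping the zone routes to the other stratum and changes scores
  flipped <- df
  flipped$zone <- ifelse(df$zone == "PZ", "TZ", "PZ")
  expect_false(identical(score_pixels(m, tab),
                         score_pixels(m, feature_table(flipped))))
})

test_that("calcified pixels are omitted from training", {
  tab <- random_feature_table(n = 900, seed = 22)
  df <- as.data.frame(tab)
  flagged <- df$patient_id == "P03"
  df$calcified[flagged] <- TRUE
  m <- train_zonal_forest(feature_table(df), run_config(n_trees = 50), 1)
  for (z in c("PZ", "TZ"))
    expect_false(any(m$strata[[z]]$patient_ids == "P03"))
})

test_that("the median post-filter matches the brute-force kernel median", {
  # constant map unchanged
  cm <- param_map("score", matrix(0.4, 20, 20))
  expect_equal(median_postfilter(cm, 3)$values, cm$values)
  # a single outlier in a uniform field is removed
  vals <- matrix(-1, 25, 25); vals[13, 13] <- 1
  out <- median_postfilter(param_map("score", vals), 5)
  expect_equal(out$values[13, 13], -1)
  # checkerboard equals the brute-force kernel median per pixel
  set.seed(2)
  cb <- matrix(rep_len(c(-1, 1), 21 * 21), 21, 21)
  cb[sample(441, 30)] <- NA
  m <- param_map("score", cb)
  r <- 4
  filt <- median_postfilter(m, r)
  g <- expand.grid(dr = -r:r, dc = -r:r)
  g <- g[g$dr^2 + g$dc^2 <= r^2, ]
  for (p in sample(which(m$valid), 40)) {
    r0 <- (p - 1) %% 21 + 1; c0 <- (p - 1) %/% 21 + 1
    rr <- r0 + g$dr; cc <- c0 + g$dc
    ok <- rr >= 1 & rr <= 21 & cc >= 1 & cc <= 21
    mem <- cb[cbind(rr[ok], cc[ok])]
    expect_equal(filt$values[p], median(mem, na.rm = TRUE),
                 tolerance = 1e-12)
  }
  # invalid pixels stay invalid
  expect_identical(filt$valid, m$valid)
})
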