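seeded_map <- function(nr = 40, nc = 40, seed = 3, name = "v") {
  set.seed(seed)
  vals <- matrix(runif(nr * nc), nr, nc)
  mask <- matrix(TRUE, nr, nc); mask[1:3, ] <- FALSE
  vals[5, 5] <- NA
  m <- param_map(name, vals)
  m$valid <- m$valid & mask
  m$values[!m$valid] <- NA
  list(map = m, mask = mask)
}

brute_members <- function(map, p, offs) {
  nr <- nrow(map$values); nc <- ncol(map$values)
  r0 <- (p - 1) %% nr + 1; c0 <- (p - 1) %/% nr + 1
  out <- c()
  for (k in seq_len(nrow(offs))) {
    rr <- r0 + offs$dr[k]; cc <- c0 + offs$dc[k]
    if (rr >= 1 && rr <= nr && cc >= 1 && cc <= nc &&
        isTRUE(map$valid[rr, cc]))
      out <- c(out, map$values[rr, cc])
  }
  out
}

circ_offs <- function(radius_mm, sp) {
  r_px <- max(1, round(radius_mm / sp))
  g <- expand.grid(dr = -r_px:r_px, dc = -r_px:r_px)
  g[g$dr^2 + g$dc^2 <= r_px^2, ]
}

test_that("relative-to-median maps are centered per image", {
  f <- seeded_map()
  # constant map maps to all zeros
  cm <- param_map("E", matrix(4.2, 10, 10))
  rel <- relative_to_median(cm, matrix(TRUE, 10, 10))
  expect_true(all(rel$values == 0))
  expect_equal(rel$name, "E.rel")
  # {1,2,3} -> {-1,0,1}
  m3 <- param_map("G", matrix(c(1, 2, 3), 1, 3))
  expect_equal(as.vector(relative_to_median(m3, matrix(TRUE, 1, 3))$values),
               c(-1, 0, 1))
  # the in-mask median of any rel map is exactly zero
  rel2 <- relative_to_median(f$map, f$mask)
  expect_identical(median(rel2$values[rel2$valid]), 0)
})

test_that("local entropy matches closed forms and the brute-force oracle", {
  sp <- 0.167
  # constant map: zero bits everywhere valid
  cm <- param_map("v", matrix(1, 20, 20))
  e0 <- local_entropy(cm, 1, sp)
  expect_true(any(e0$valid))
  expect_true(all(e0$values[e0$valid] == 0))
  # a kernel holding exactly two equally frequent values: one bit
  vals <- matrix(NA_real_, 20, 20)
  pts <- cbind(10, 3:12)
  vals[pts] <- rep(c(0, 1), 5)
  m2 <- param_map("v", vals)
  e2 <- local_entropy(m2, 2, sp, min_members = 10)
  expect_equal(e2$values[10, 7], 1)
  # seeded random map equals the brute-force histogram entropy per pixel
  f <- seeded_map(seed = 13)
  ent <- local_entropy(f$map, 1, sp)
  x <- f$map$values[f$map$valid]
  rng <- quantile(x, c(0.01, 0.99), names = FALSE)
  edges <- seq(rng[1], rng[2], length.out = 33)
  offs <- circ_offs(1, sp)
  for (p in sample(which(ent$valid), 25)) {
    mem <- brute_members(f$map, p, offs)
    bins <- pmin(pmax(findInterval(mem, edges, rightmost.closed = TRUE),
                      1), 32)
    pr <- table(bins) / length(bins)
    expect_equal(ent$values[p], -sum(pr * log2(pr)), tolerance = 1e-12)
  }
  # fewer than 10 valid kernel members invalidates the estimate
  vals9 <- matrix(NA_real_, 20, 20)
  vals9[cbind(10, 3:11)] <- rep(c(0, 1), length.out = 9)
  e9 <- local_entropy(param_map("v", vals9), 2, sp, min_members = 10)
  expect_false(any(e9$valid))
})

test_that("local variance is the unbiased kernel variance", {
  sp <- 0.167
  cm <- param_map("v", matrix(3, 15, 15))
  v0 <- local_variance(cm, 2, sp)
  expect_true(all(v0$values[v0$valid] == 0))
  # two-member kernel {0, 2} has unbiased variance 2
  vals <- matrix(NA_real_, 9, 9)
  vals[5, 5] <- 0; vals[5, 6] <- 2
  mv <- local_variance(param_map("v", vals), 0.2, c(0.167, 0.167))
  expect_equal(mv$values[5, 5], 2)
  # brute-force agreement on a seeded map
  f <- seeded_map(seed = 19)
  va <- local_variance(f$map, 2, sp)
  offs <- circ_offs(2, sp)
  for (p in sample(which(va$valid), 25)) {
    expect_equal(va$values[p], var(brute_members(f$map, p, offs)),
                 tolerance = 1e-12)
  }
})

test_that("bright calcifications are detected and dark spots are not", {
  ph <- calc_phantom()
  det <- detect_calcifications(ph$img, ph$mask, ph$spacing)
  expect_gte(mean(det[ph$disks]), 0.90)
  expect_lte(sum(det & !ph$disks) / sum(ph$mask), 0.01)
  # hypoechoic (dark) disks are not flagged
  img2 <- ph$img
  img2[ph$disks] <- 0.1 * mean(ph$img[!ph$disks])
  det2 <- detect_calcifications(img2, ph$mask, ph$spacing)
  expect_equal(sum(det2 & ph$disks), 0)
  # a uniform image yields an empty mask
  expect_equal(sum(detect_calcifications(matrix(1, 60, 60),
                                         matrix(TRUE, 60, 60),
                                         ph$spacing)), 0)
})

test_that("radiomic expansion yields 84 manifest-ordered features", {
  set.seed(4)
  nr <- 20; nc <- 24; sp <- 0.5
  mask <- matrix(FALSE, nr, nc); mask[4:17, 4:21] <- TRUE
  maps <- lapply(setNames(nm = param_catalog()), function(nm) {
    vals <- matrix(rnorm(nr * nc), nr, nc)
    vals[!mask] <- NA
    param_map(nm, vals)
  })
  fe <- radiomic_expand(maps, mask, sp)
  expect_equal(ncol(fe$features), 84)
  expect_identical(colnames(fe$features), feature_manifest())
  expect_equal(nrow(fe$features), sum(mask))
  # permuting the input map order changes nothing
  fe2 <- radiomic_expand(maps[rev(param_catalog())], mask, sp)
  expect_identical(fe2$features, fe$features)
  # a fully invalid base map invalidates its six columns
  maps$E <- param_map("E", matrix(NA_real_, nr, nc))
  fe3 <- radiomic_expand(maps, mask, sp)
  ecols <- paste0("E", c("", ".rel", ".ent1", ".ent2", ".ent3", ".var2"))
  expect_true(all(is.na(fe3$features[, ecols])))
  # a missing base map fails loudly
  expect_error(radiomic_expand(maps[-1], mask, sp), "missing base maps")
  # grid mismatch fails loudly
  maps$Pe <- param_map("Pe", matrix(0, 5, 5))
  expect_error(radiomic_expand(maps, mask, sp), "grid")
})
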