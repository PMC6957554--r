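bolus_tic <- function(t, scale = 1, mu = 20, kappa = 1, t0 = 5) {
  tic(t, scale * ldrw_curve(t, 100, kappa, mu, t0))
}

test_that("spatiotemporal correlation matches its definition", {
  t <- seq(0, 120, by = 0.2)
  ctr <- bolus_tic(t)
  # identical neighbors correlate perfectly
  r <- spatiotemporal_correlation(ctr, list(ctr, ctr, ctr))
  expect_equal(r, 1, tolerance = 1e-12)
  # orthogonal signals (sine vs cosine over whole periods) correlate to 0
  wide <- run_config(corr_window_s = c(-1e6, 1e6))
  ts <- seq(0, 100 - 0.1, by = 0.1)
  sine <- tic(ts, sin(2 * pi * 0.1 * ts))
  cosine <- tic(ts, cos(2 * pi * 0.1 * ts))
  expect_lt(abs(spatiotemporal_correlation(sine, list(cosine), wide)), 1e-6)
  # zero-variance center is invalid
  expect_true(is.na(spatiotemporal_correlation(tic(t, rep(0, length(t))),
                                               list(ctr))))
  # seeded random-walk neighborhood equals the brute-force mean of
  # pairwise Pearson coefficients
  set.seed(31)
  walks <- lapply(1:12, function(i) tic(t, cumsum(rnorm(length(t)))))
  ctr2 <- tic(t, cumsum(rnorm(length(t))))
  cfg <- run_config()
  r2 <- spatiotemporal_correlation(ctr2, walks, cfg)
  y0 <- ctr2$y - min(ctr2$y)
  pk <- max(y0); at <- t[which(y0 >= 0.05 * pk)[1]]
  w <- t >= at - 5 & t <= at + 60
  oracle <- mean(vapply(walks, function(nb) cor(ctr2$y[w], nb$y[w]), 0))
  expect_equal(r2, oracle, tolerance = 1e-12)
})

test_that("spectral coherence is delay-invariant and bounded", {
  t <- seq(0, 120, by = 0.2)
  ctr <- bolus_tic(t)
  expect_equal(spectral_coherence(ctr, list(ctr)), 1, tolerance = 1e-9)
  # a 2-s delayed copy keeps in-band coherence near 1 (1-Hz sampling, so
  # the 0-0.5 Hz analysis band spans the full spectrum and the Welch
  # segments are long against the delay)
  t1 <- 0:119
  ctr1 <- tic(t1, ldrw_curve(t1, 100, 1, 20, 5))
  del1 <- tic(t1, ldrw_curve(t1, 100, 1, 20, 7))
  expect_gte(spectral_coherence(ctr1, list(del1)), 0.95)
  # independent white noise: finite-sample coherence bias stays small
  set.seed(8)
  vals <- replicate(50, {
    a <- tic(t, rnorm(length(t)))
    b <- tic(t, rnorm(length(t)))
    spectral_coherence(a, list(b))
  })
  expect_lt(mean(vals), 0.35)
  # short records are refused
  expect_error(spectral_coherence(tic(1:10, 1:10), list(tic(1:10, 1:10))),
               "64")
})

test_that("correlation and coherence are invariant to affine intensity scaling", {
  t <- seq(0, 120, by = 0.2)
  set.seed(12)
  ctr <- bolus_tic(t)
  nbs <- lapply(1:5, function(i)
    tic(t, ldrw_curve(t, 100, 1, 18 + i, 5) + rnorm(length(t), 0, 0.1)))
  r0 <- spatiotemporal_correlation(ctr, nbs)
  rho0 <- spectral_coherence(ctr, nbs)
  scaled <- lapply(seq_along(nbs), function(i) {
    x <- nbs[[i]]; x$y <- (1 + i) * x$y + 3 * i; x
  })
  ctr2 <- ctr; ctr2$y <- 2.5 * ctr2$y + 7
  expect_equal(spatiotemporal_correlation(ctr2, scaled), r0,
               tolerance = 1e-9)
  expect_equal(spectral_coherence(ctr2, scaled), rho0, tolerance = 1e-9)
})

test_that("convection-dispersion identification inverts its forward model", {
  t <- seq(0, 120, by = 0.2); dt <- 0.2
  src <- ldrw_curve(t, 100, 0.8, 18, 8)
  ring <- ring_kernel(0.167, 0.5, 2.0, 16)
  nbs <- lapply(ring$dist_mm, function(d) {
    y <- convolve(src, rev(conv_disp_green(t, d, 1.0, 0.2)),
                  type = "open")[seq_along(t)] * dt
    tic(t, y)
  })
  est <- identify_conv_disp(tic(t, src), nbs, ring$dist_mm)
  expect_true(est$valid)
  expect_lt(abs(est$v / 1.0 - 1), 0.10)
  expect_lt(abs(est$D / 0.2 - 1), 0.20)
  # Pe = v * L / D holds exactly
  expect_identical(est$Pe, est$v * est$L_mm / est$D)
  # neighbors identical to the center carry no transport information
  same <- lapply(ring$dist_mm, function(d) tic(t, src))
  est0 <- identify_conv_disp(tic(t, src), same, ring$dist_mm)
  expect_true(!est0$valid || est0$v < 0.1)
  # fewer than 8 neighbors are refused
  expect_error(identify_conv_disp(tic(t, src), nbs[1:4], ring$dist_mm[1:4]),
               "8 neighbors")
})

test_that("ring kernels respect their bounds and angular decimation", {
  ring <- ring_kernel(c(0.167, 0.167), 0.5, 2.0)
  expect_true(all(ring$dist_mm >= 0.5 & ring$dist_mm <= 2.0))
  expect_gte(nrow(ring), 8)
  capped <- ring_kernel(0.167, 0.5, 2.0, max_members = 24)
  expect_lte(nrow(capped), 24)
  expect_gte(nrow(capped), 8)
  expect_error(ring_kernel(0.167, 2, 1), "inner")
})

test_that("dispersion maps behave on homogeneous and empty planes", {
  set.seed(21)
  nt <- 601; nr <- 10; nc <- 10
  t <- seq(0, 120, length.out = nt)
  y <- ldrw_curve(t, 80, 0.8, 22, 10)
  frames <- array(rep(y, nr * nc), c(nt, nr, nc)) +
    array(rnorm(nt * nr * nc, 0, 0.01 * max(y)), c(nt, nr, nc))
  frames[frames < 0] <- 0
  dce <- dce_plane(frames, t, 0.5)
  mask <- matrix(TRUE, nr, nc)
  maps <- dispersion_maps(dce, mask, run_config(ring_inner_mm = 0.4))
  rv <- maps$r$values[maps$r$valid]
  expect_gt(length(rv), 0)
  expect_true(all(rv > 0.99))
  empty <- dispersion_maps(dce, matrix(FALSE, nr, nc))
  expect_false(any(empty$v$valid))
})
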