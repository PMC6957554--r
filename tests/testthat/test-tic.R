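test_that("preprocessing removes the baseline and rejects short records", {
  t <- seq(0, 120, by = 0.2)
  # constant curve collapses to zero after baseline subtraction
  x <- preprocess_tic(tic(t, rep(7.5, length(t))))
  expect_true(x$valid)
  expect_lt(max(abs(x$y)), 1e-9)
  # 5-sample curve is too short to fit
  x2 <- preprocess_tic(tic(1:5, 1:5))
  expect_false(x2$valid)
  # low-pass: white noise at 5% of peak is suppressed to < 2% RMS
  # (raw intensities carry a positive baseline, as in linear-scale data)
  set.seed(10)
  t2 <- seq(0, 120, by = 0.1)
  clean <- ldrw_curve(t2, 100, 1, 20, 5)
  noisy <- clean + 2 + rnorm(length(t2), 0, 0.05 * max(clean))
  filt <- preprocess_tic(tic(t2, pmax(noisy, 0)))
  rms <- sqrt(mean((filt$y - clean)^2))
  expect_lt(rms, 0.02 * max(clean))
})

test_that("noiseless LDRW curves are refit with sub-percent accuracy", {
  t <- seq(0, 120, by = 0.1)
  for (mu in c(10, 40)) {
    for (kappa in c(0.25, 4)) {
      y <- ldrw_curve(t, 50, kappa, mu, 5)
      f <- fit_ldrw(tic(t, y))
      expect_true(f$converged)
      expect_lt(abs(f$mu / mu - 1), 0.01)
      expect_lt(abs(f$kappa / kappa - 1), 0.01)
      expect_lt(abs(f$alpha / 50 - 1), 0.01)
    }
  }
  # all-zero curve is invalid
  expect_false(fit_ldrw(tic(t, rep(0, length(t))))$converged)
})

test_that("fitted alpha equals the numerical integral of the fitted model", {
  t <- seq(0, 120, by = 0.1)
  y <- ldrw_curve(t, 80, 0.7, 25, 8)
  f <- fit_ldrw(tic(t, y))
  tt <- seq(f$t0 + 1e-6, 1000, by = 0.02)
  integral <- sum(ldrw_curve(tt, f$alpha, f$kappa, f$mu, f$t0)) * 0.02
  expect_lt(abs(integral / f$alpha - 1), 0.01)
})

test_that("the fit is scale- and time-shift-equivariant", {
  t <- seq(0, 120, by = 0.1)
  y <- ldrw_curve(t, 60, 1.2, 15, 6)
  f0 <- fit_ldrw(tic(t, y))
  # intensity scaling moves alpha (and PI), not the kinetic parameters
  f1 <- fit_ldrw(tic(t, 3 * y))
  expect_equal(f1$alpha / f0$alpha, 3, tolerance = 1e-3)
  expect_equal(f1$mu, f0$mu, tolerance = 1e-4)
  expect_equal(f1$kappa, f0$kappa, tolerance = 1e-4)
  h0 <- heuristic_params(tic(t, y)); h1 <- heuristic_params(tic(t, 3 * y))
  expect_equal(h1$PI / h0$PI, 3, tolerance = 1e-9)
  expect_equal(h1$AT, h0$AT); expect_equal(h1$WIT, h0$WIT)
  # time shift moves t0/AT/PT, not mu, kappa, alpha, WIT
  y2 <- ldrw_curve(t, 60, 1.2, 15, 16)
  f2 <- fit_ldrw(tic(t, y2))
  expect_equal(f2$t0 - f0$t0, 10, tolerance = 0.05)
  expect_equal(f2$mu, f0$mu, tolerance = 1e-3)
  expect_equal(f2$kappa, f0$kappa, tolerance = 1e-3)
  expect_equal(f2$alpha, f0$alpha, tolerance = 0.1)
  h2 <- heuristic_params(tic(t, y2))
  expect_equal(h2$AT - h0$AT, 10, tolerance = 0.2)
  expect_equal(h2$WIT, h0$WIT, tolerance = 0.2)
})

test_that("heuristic bolus parameters match their closed-form crossings", {
  # piecewise-linear bolus: flat until 10 s, ramp to 1.0 at 30 s, decay
  t <- 0:60
  y <- ifelse(t < 10, 0, ifelse(t <= 30, (t - 10) / 20,
                                pmax(0, 1 - (t - 30) / 40)))
  h <- heuristic_params(tic(t, y))
  expect_equal(h$PI, 1.0)
  expect_equal(h$PT, 30)
  expect_equal(h$AT, 11)   # 5% crossing of the ramp
  expect_equal(h$WIT, 16)  # 28 s (90%) - 12 s (10%)
  # zero curve has no bolus
  expect_false(heuristic_params(tic(t, rep(0, 61)))$valid)
  # peak time of an LDRW curve equals its dense argmax within one sample
  t2 <- seq(0, 120, by = 0.2)
  y2 <- ldrw_curve(t2, 100, 1, 20, 5)
  h2 <- heuristic_params(tic(t2, y2))
  td <- seq(0, 120, by = 1e-3)
  expect_lt(abs(h2$PT - td[which.max(ldrw_curve(td, 100, 1, 20, 5))]), 0.2)
})

test_that("noisy replicates keep the median transit-time error below 5%", {
  set.seed(77)
  t <- seq(0, 120, by = 0.2)
  clean <- ldrw_curve(t, 100, 1, 20, 5)
  sigma <- sqrt(mean(clean^2)) / 10^(20 / 20)  # SNR 20 dB
  errs <- replicate(50, {
    y <- pmax(clean + rnorm(length(t), 0, sigma), 0)
    f <- fit_ldrw(preprocess_tic(tic(t, y)))
    abs(f$mu / 20 - 1)
  })
  expect_lte(median(errs, na.rm = TRUE), 0.05)
})

test_that("per-pixel bolus maps are constant on a homogeneous plane", {
  set.seed(5)
  nt <- 301; nr <- 7; nc <- 8
  t <- seq(0, 120, length.out = nt)
  y <- ldrw_curve(t, 80, 0.8, 22, 10)
  frames <- array(rep(y, nr * nc), c(nt, nr, nc))
  dce <- dce_plane(frames, t, 0.5)
  mask <- matrix(TRUE, nr, nc)
  maps <- tic_maps(dce, mask)
  for (nm in c("mu", "kappa", "alpha", "PT", "PI", "WIT", "AT")) {
    vals <- maps[[nm]]$values[maps[[nm]]$valid]
    expect_gt(length(vals), 0)
    expect_lt(diff(range(vals)), 1e-6 * max(abs(vals)))
  }
  # an empty mask produces empty maps without error
  maps0 <- tic_maps(dce, matrix(FALSE, nr, nc))
  expect_false(any(maps0$mu$valid))
})
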