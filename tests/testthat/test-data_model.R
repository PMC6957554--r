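make_tiny_bundle <- function(seed = 1) {
  set.seed(seed)
  nt <- 25; nr <- 10; nc <- 12
  frames <- array(runif(nt * nr * nc, 0, 50), c(nt, nr, nc))
  dce <- dce_plane(frames, seq(0, 120, length.out = nt), c(0.5, 0.5),
                   "Pa", "mid")
  prostate <- matrix(FALSE, nr, nc); prostate[3:8, 3:10] <- TRUE
  zone <- matrix(0L, nr, nc)
  zone[prostate] <- 1L; zone[5:6, 4:8] <- 2L
  zone[!prostate] <- 0L
  roi <- matrix(0L, nr, nc); roi[4, 4:6] <- 1L; roi[7, 7:9] <- 2L
  calc <- matrix(FALSE, nr, nc); calc[3, 3] <- TRUE
  plane_bundle(dce, bmode = matrix(runif(nr * nc), nr, nc),
               swe = matrix(runif(nr * nc, 5, 80), nr, nc),
               prostate_mask = prostate, zone_mask = zone,
               calcification_mask = calc, roi_labels = roi)
}

test_that("bundle invariants are enforced at construction", {
  b <- make_tiny_bundle()
  expect_s3_class(b, "plane_bundle")
  # zone label outside the prostate is rejected
  zone_bad <- b$zone_mask; zone_bad[1, 1] <- 1L
  expect_error(plane_bundle(b$dce, b$bmode, b$swe, b$prostate_mask,
                            zone_bad, b$calcification_mask, b$roi_labels),
               "outside the prostate")
  # ROI outside the prostate is rejected
  roi_bad <- b$roi_labels; roi_bad[1, 1] <- 2L
  expect_error(plane_bundle(b$dce, b$bmode, b$swe, b$prostate_mask,
                            b$zone_mask, b$calcification_mask, roi_bad),
               "inside the prostate")
  # shape mismatch names shapes instead of resampling
  expect_error(plane_bundle(b$dce, b$bmode[1:5, ], b$swe, b$prostate_mask,
                            b$zone_mask),
               "does not match")
  # timestamps must be strictly increasing and match the frame count
  expect_error(dce_plane(b$dce$frames, rev(b$dce$timestamps), 0.5),
               "strictly increasing")
  expect_error(dce_plane(b$dce$frames, 1:10, 0.5), "length")
})

test_that("a 2-minute loop at 5 Hz yields 601 strictly increasing timestamps", {
  nt <- 601
  frames <- array(0, c(nt, 4, 4))
  ts <- seq(0, 120, length.out = nt)
  dce <- dce_plane(frames, ts, 0.167)
  expect_length(dce$timestamps, 601)
  expect_true(all(diff(dce$timestamps) > 0))
  expect_equal(mean(1 / diff(dce$timestamps)), 5, tolerance = 1e-9)
})

test_that("bundles round-trip through disk exactly (NIfTI) and to float32 (TIFF)", {
  b <- make_tiny_bundle()
  d1 <- withr::local_tempdir()
  write_plane_bundle(b, d1, format = "nifti")
  b1 <- load_plane_bundle(d1)
  expect_identical(b1$dce$frames, b$dce$frames)
  expect_identical(b1$swe, b$swe)
  expect_identical(b1$zone_mask, b$zone_mask)
  expect_identical(b1$roi_labels, b$roi_labels)
  expect_identical(b1$calcification_mask, b$calcification_mask)
  expect_equal(b1$dce$timestamps, b$dce$timestamps)

  d2 <- withr::local_tempdir()
  write_plane_bundle(b, d2, format = "tiff")
  b2 <- load_plane_bundle(d2)
  expect_equal(b2$dce$frames, b$dce$frames, tolerance = 1e-6)
  expect_equal(b2$bmode, b$bmode, tolerance = 1e-6)
  expect_identical(b2$zone_mask, b$zone_mask)   # labels stay exact
  expect_identical(b2$prostate_mask, b$prostate_mask)

  # a missing raster names its role
  file.remove(file.path(d2, "swe.tif"))
  expect_error(load_plane_bundle(d2), "swe")
})

test_that("intensity linearization follows the 10^(x*DR/2550) law", {
  expect_equal(linearize_intensity(0, 40), 1)
  expect_equal(linearize_intensity(255, 40), 1e4)
  x <- 0:255
  expect_equal(compress_intensity(linearize_intensity(x, 40), 40), x,
               tolerance = 1e-12)
  expect_error(linearize_intensity(10, -3), "dynamic_range_db")
  # monotone
  expect_true(all(diff(linearize_intensity(x, 40)) > 0))
})

test_that("feature tables round-trip losslessly and validate their manifest", {
  tab <- random_feature_table(n = 100, n_patients = 8, seed = 3)
  f <- withr::local_tempfile(fileext = ".csv")
  write_feature_table(tab, f)
  tab2 <- read_feature_table(f)
  expect_identical(ft_manifest(tab2), ft_manifest(tab))
  expect_equal(as.data.frame(tab2), as.data.frame(tab), tolerance = 1e-12)

  # reordered feature columns vs manifest fail on read
  lines <- readLines(f)
  hdr <- strsplit(lines[2], ",")[[1]]
  i <- match(sprintf('"%s"', c("Pe", "v")), hdr)
  hdr[i] <- hdr[rev(i)]
  lines[2] <- paste(hdr, collapse = ",")
  writeLines(lines, f)
  expect_error(read_feature_table(f), "manifest")

  # empty table (header only) reads back with 0 rows
  empty <- tab[0, ]
  attr(empty, "manifest") <- ft_manifest(tab)
  class(empty) <- c("feature_table", "data.frame")
  f2 <- withr::local_tempfile(fileext = ".csv")
  write_feature_table(empty, f2)
  expect_equal(nrow(read_feature_table(f2)), 0)
})

test_that("run configurations round-trip through YAML", {
  cfg <- run_config(n_trees = 123, ring_outer_mm = 1.7, seed = 9)
  f <- withr::local_tempfile(fileext = ".yaml")
  write_run_config(cfg, f)
  cfg2 <- read_run_config(f)
  expect_equal(cfg2, cfg)
  expect_error(run_config(subsample_fraction = 0), "subsample")
  expect_error(run_config(ring_inner_mm = 3, ring_outer_mm = 2), "ring")
})

test_that("feature rows outside the prostate zones are rejected", {
  tab <- random_feature_table(n = 20, n_patients = 8)
  df <- as.data.frame(tab)
  df$zone[1] <- "outside"
  expect_error(feature_table(df), "zone")
  df2 <- as.data.frame(tab)
  df2$label[1] <- "unknown"
  expect_error(feature_table(df2), "label")
})
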