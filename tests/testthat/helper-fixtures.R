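# Shared fixtures. Everything is generated in code; the expensive
# synthetic cohort (and its extracted features) is built once per test
# session and reused by the forest, evaluation and acceptance tests.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, .fixture_cache)) assign(key, expr, .fixture_cache)
  get(key, .fixture_cache)
}

# Reduced-resolution study conditions used throughout the tests: the
# spatial grid is coarsened to 0.5 mm/px (36 x 48 px) so mm-scale anatomy
# is preserved while per-pixel model fitting stays fast; the median
# post-filter radius is kept at ~2.5 mm physical (5 px at this spacing).
test_sim_config <- function(...) {
  sim_config(grid = c(36, 48), pixel_spacing = 0.5, ...)
}

test_run_config <- function(...) {
  run_config(median_filter_radius_px = 5, ...)
}

# A single synthetic plane bundle (fast; ~1 s).
test_bundle <- function(seed = 123, parity = 0, ...) {
  cfg <- test_sim_config(n_patients = 1, planes_per_patient = 1, ...)
  simulate_patient(cfg, seed, "P01", parity)
}

# Speckle-texture frame for registration tests.
speckle_frame <- function(nr = 72, nc = 96, seed = 1) {
  set.seed(seed)
  gaussian_smooth_for_tests(matrix(stats::rgamma(nr * nc, 3, 3), nr, nc), 1)
}

# Minimal local re-implementation (tests must not reach into internals
# for fixture construction).
gaussian_smooth_for_tests <- function(x, sigma) {
  half <- ceiling(4 * sigma)
  k <- exp(-0.5 * ((-half:half) / sigma)^2)
  k <- k / sum(k)
  pad <- function(m) rbind(m[rep(1, half), , drop = FALSE], m,
                           m[rep(nrow(m), half), , drop = FALSE])
  one <- function(m) {
    f <- stats::filter(pad(m), k, sides = 2)
    matrix(f[(half + 1):(half + nrow(m)), ], nrow(m), ncol(m))
  }
  t(one(t(one(x))))
}

# Random labeled feature table: n patients, zones mixed within patients,
# labels tied to the named feature (or random for NULL).
random_feature_table <- function(n = 1200, n_patients = 10, seed = 42,
                                 driver = "Pe") {
  set.seed(seed)
  man <- feature_manifest()
  X <- matrix(rnorm(n * length(man)), n, dimnames = list(NULL, man))
  lab <- if (is.null(driver)) sample(c("benign", "malignant"), n, TRUE) else
    ifelse(X[, driver] > 0, "malignant", "benign")
  df <- data.frame(
    patient_id = rep(sprintf("P%02d", seq_len(n_patients)), length.out = n),
    plane_id = rep(c("apex", "mid", "base"), length.out = n),
    row = 1L, col = 1L,
    zone = rep(rep(c("PZ", "TZ"), each = 3), length.out = n),
    label = lab, calcified = FALSE, stringsAsFactors = FALSE)
  feature_table(cbind(df, as.data.frame(X)))
}

# The end-to-end synthetic study: 12-patient cohort, full feature
# extraction, labeled table and leave-one-patient-out evaluation.
e2e_state <- function() {
  cached("e2e", {
    cfg <- test_sim_config(n_patients = 12)
    rc <- test_run_config()
    cohort <- simulate_cohort(cfg, seed = 11)
    planes <- cohort_features(cohort, rc)
    tab <- build_feature_table(planes)
    cv <- lopo_crossval(tab, rc, seed = 21, planes = planes)
    list(cohort = cohort, planes = planes, table = tab, cv = cv,
         config = rc)
  })
}

# Calcification phantom at clinical resolution: speckle background with
# one 1.2-mm and one 3.6-mm bright disk at 5x the background mean.
calc_phantom <- function(seed = 9) {
  set.seed(seed)
  nr <- 144; nc <- 192; sp <- 0.167
  bg <- matrix(stats::rgamma(nr * nc, 4, 4), nr, nc) * 0.5
  r <- matrix(seq_len(nr), nr, nc); cc <- matrix(seq_len(nc), nr, nc, TRUE)
  pm <- ((r - 72) / 50)^2 + ((cc - 96) / 70)^2 <= 1
  disk <- function(c0, rad_mm) {
    (r - c0[1])^2 + (cc - c0[2])^2 <= round(rad_mm / sp)^2
  }
  m_small <- disk(c(60, 70), 0.6)
  m_large <- disk(c(90, 120), 1.8)
  img <- bg
  img[m_small | m_large] <- 5 * mean(bg)
  list(img = img, mask = pm, disks = m_small | m_large, spacing = sp)
}
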