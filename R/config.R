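#' Analysis run configuration
#'
#' Collects every tunable of the feature-extraction and classification
#' pipeline in one validated object. Physical kernel sizes are given in mm
#' and converted to pixels per plane using the plane's pixel spacing;
#' forest hyper-parameters follow the published recipe (1000 trees, a
#' 1/1000 bootstrap per tree, six training patients discarded per tree,
#' cross-entropy splits, maximum depth 50).
#'
#' @param entropy_radii_mm Radii (mm) of the circular kernels used for the
#'   multiscale local-entropy radiomics.
#' @param variance_radius_mm Radius (mm) of the local-variance kernel.
#' @param entropy_bins Number of histogram bins for local entropy, spanning
#'   the in-mask 1st-99th percentile range of each map.
#' @param ring_inner_mm,ring_outer_mm Ring-kernel bounds (mm) for the
#'   neighborhood dispersion estimators.
#' @param ring_max_members Upper bound on ring members actually used per
#'   pixel; members are decimated uniformly in angle beyond this count.
#' @param at_threshold Fraction of peak intensity defining the appearance
#'   time crossing.
#' @param wit_fractions Lower/upper fractions of peak intensity whose rise
#'   times define the wash-in time.
#' @param lowpass_hz Cut-off (Hz) of the zero-phase low-pass applied to
#'   time-intensity curves before fitting.
#' @param baseline_window_s Length (s) of the early-record window whose
#'   median defines the pre-arrival baseline.
#' @param coherence_band_hz Two-element band (Hz) over which magnitude
#'   squared coherence is averaged.
#' @param coherence_segment Welch segment length in samples (50\% overlap).
#' @param deconv_lambda Tikhonov regularization factor, relative to the mean
#'   input power, for impulse-response estimation.
#' @param corr_window_s Two-element window, in seconds relative to the
#'   center pixel's appearance time, over which spatiotemporal correlation
#'   is evaluated.
#' @param calc_sigmas_mm Standard deviations (mm) of the two Gaussian
#'   matched filters used for calcification detection.
#' @param calc_k Threshold, in in-mask standard deviations above the mean
#'   filter response, above which a pixel is considered calcified.
#' @param calc_min_px Minimum connected-component area (px) retained in the
#'   calcification mask.
#' @param n_trees Trees per zonal stratum.
#' @param subsample_fraction Fraction of the (post-discard) training rows
#'   bootstrapped per tree.
#' @param min_tree_rows Lower bound on the per-tree bootstrap size; guards
#'   against degenerate trees on small synthetic cohorts.
#' @param patients_discarded_per_tree Number of training patients dropped
#'   entirely before growing each tree.
#' @param max_depth Maximum tree depth.
#' @param min_leaf Minimum samples per leaf.
#' @param median_filter_radius_px Radius (px) of the circular median filter
#'   applied to the multiparametric score map.
#' @param dynamic_range_db Assumed log-compression dynamic range (dB) when a
#'   loader is told its input is log-compressed.
#' @param seed Optional integer seed recorded in output manifests.
#' @return An object of class `mpus_config` (a validated list).
#' @export
run_config <- function(entropy_radii_mm = c(1, 2, 3),
                       variance_radius_mm = 2,
                       entropy_bins = 32,
                       ring_inner_mm = 0.5,
                       ring_outer_mm = 2.0,
                       ring_max_members = 24,
                       at_threshold = 0.05,
                       wit_fractions = c(0.10, 0.90),
                       lowpass_hz = 0.5,
                       baseline_window_s = 10,
                       coherence_band_hz = c(0, 0.5),
                       coherence_segment = 32,
                       deconv_lambda = 0.05,
                       corr_window_s = c(-5, 60),
                       calc_sigmas_mm = c(0.6, 1.8),
                       calc_k = 3,
                       calc_min_px = 3,
                       n_trees = 1000,
                       subsample_fraction = 1 / 1000,
                       min_tree_rows = 100,
                       patients_discarded_per_tree = 6,
                       max_depth = 50,
                       min_leaf = 5,
                       median_filter_radius_px = 15,
                       dynamic_range_db = 40,
                       seed = NULL) {
  cfg <- list(
    entropy_radii_mm = entropy_radii_mm,
    variance_radius_mm = variance_radius_mm,
    entropy_bins = entropy_bins,
    ring_inner_mm = ring_inner_mm,
    ring_outer_mm = ring_outer_mm,
    ring_max_members = ring_max_members,
    at_threshold = at_threshold,
    wit_fractions = wit_fractions,
    lowpass_hz = lowpass_hz,
    baseline_window_s = baseline_window_s,
    coherence_band_hz = coherence_band_hz,
    coherence_segment = coherence_segment,
    deconv_lambda = deconv_lambda,
    corr_window_s = corr_window_s,
    calc_sigmas_mm = calc_sigmas_mm,
    calc_k = calc_k,
    calc_min_px = calc_min_px,
    n_trees = n_trees,
    subsample_fraction = subsample_fraction,
    min_tree_rows = min_tree_rows,
    patients_discarded_per_tree = patients_discarded_per_tree,
    max_depth = max_depth,
    min_leaf = min_leaf,
    median_filter_radius_px = median_filter_radius_px,
    dynamic_range_db = dynamic_range_db,
    seed = seed
  )
  class(cfg) <- "mpus_config"
  validate_run_config(cfg)
}

#' @rdname run_config
#' @param config An `mpus_config` object to validate.
#' @export
validate_run_config <- function(config) {
  stopifnot(inherits(config, "mpus_config"))
  with(config, {
    if (any(entropy_radii_mm <= 0) || variance_radius_mm <= 0)
      stop("kernel radii must be > 0")
    if (ring_inner_mm <= 0 || ring_outer_mm <= ring_inner_mm)
      stop("ring kernel requires 0 < inner < outer radius")
    if (subsample_fraction <= 0 || subsample_fraction > 1)
      stop("subsample_fraction must lie in (0, 1]")
    if (n_trees < 1 || max_depth < 1 || min_leaf < 1)
      stop("forest parameters must be positive integers")
    if (entropy_bins < 2) stop("entropy_bins must be >= 2")
    if (at_threshold <= 0 || at_threshold >= 1)
      stop("at_threshold must lie in (0, 1)")
    if (length(wit_fractions) != 2 || wit_fractions[1] >= wit_fractions[2])
      stop("wit_fractions must be increasing fractions of peak intensity")
    if (dynamic_range_db <= 0) stop("dynamic_range_db must be > 0")
    if (median_filter_radius_px < 1) stop("median filter radius must be >= 1 px")
  })
  invisible(config)
}

# Resolve a config argument: NULL -> defaults.
as_run_config <- function(config) {
  if (is.null(config)) run_config() else validate_run_config(config)
}
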