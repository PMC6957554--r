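#' @useDynLib mpus, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats fft median optim quantile rbinom rnorm rpois runif sd
#'   var cor pt pnorm setNames complete.cases
#' @importFrom utils head read.csv write.csv
"_PACKAGE"

# Zone label codes shared by masks and tables.
ZONE_OUTSIDE <- 0L
ZONE_PZ <- 1L
ZONE_TZ <- 2L

# ROI label codes.
ROI_UNLABELED <- 0L
ROI_BENIGN <- 1L
ROI_MALIGNANT <- 2L

#' Catalog of base parametric maps
#'
#' The fourteen per-pixel parameters combined by the classifier: the
#' contrast-dispersion set (Peclet number `Pe`, velocity `v`, dispersion
#' `D`, spatiotemporal correlation `r`, spectral coherence `rho`), the
#' bolus-model set (`kappa`, `mu`, `alpha`), the heuristic bolus set
#' (`WIT`, `PT`, `AT`, `PI`), the shear-wave Young's modulus `E`, and the
#' B-mode gray level `G`.
#'
#' @return Character vector of base map names, in canonical order.
#' @export
param_catalog <- function() {
  c("Pe", "v", "D", "r", "rho", "kappa", "mu", "alpha",
    "WIT", "PT", "AT", "PI", "E", "G")
}

param_units <- function() {
  c(Pe = "-", v = "mm/s", D = "mm^2/s", r = "-", rho = "-",
    kappa = "1/s", mu = "s", alpha = "a.u.*s",
    WIT = "s", PT = "s", AT = "s", PI = "a.u.",
    E = "kPa", G = "a.u.")
}

radiomic_suffixes <- function() c("", ".rel", ".ent1", ".ent2", ".ent3", ".var2")

#' Full per-pixel feature manifest
#'
#' Every base map expands into six per-pixel features: the value itself,
#' the value relative to the in-prostate median (`.rel`), local entropy at
#' three kernel scales (`.ent1`, `.ent2`, `.ent3`) and local variance in a
#' 2-mm kernel (`.var2`), for 84 features in total.
#'
#' @return Character vector of 84 feature column names in canonical order.
#' @export
feature_manifest <- function() {
  as.vector(t(outer(param_catalog(), radiomic_suffixes(), paste0)))
}

#' Construct a DCE-US plane
#'
#' A contrast-enhanced cine loop for one imaging plane: a stack of frames
#' over roughly two minutes after bolus injection, with per-frame
#' timestamps and the physical pixel spacing.
#'
#' @param frames Numeric array indexed `(time, row, col)`, linear-scale
#'   intensities (a.u.), non-negative.
#' @param timestamps Seconds from injection, strictly increasing, one per
#'   frame.
#' @param pixel_spacing mm per pixel as `(row, col)`; a scalar is recycled.
#' @param patient_id,plane_id Opaque identifiers (plane conventionally one
#'   of `"apex"`, `"mid"`, `"base"`).
#' @return An object of class `dce_plane`.
#' @export
dce_plane <- function(frames, timestamps, pixel_spacing,
                      patient_id = "p0", plane_id = "mid") {
  if (length(dim(frames)) != 3)
    stop("frames must be a 3-D (time, row, col) array")
  if (length(pixel_spacing) == 1) pixel_spacing <- rep(pixel_spacing, 2)
  x <- structure(
    list(frames = frames, timestamps = as.numeric(timestamps),
         pixel_spacing = as.numeric(pixel_spacing),
         patient_id = as.character(patient_id),
         plane_id = as.character(plane_id)),
    class = "dce_plane")
  validate_dce_plane(x)
}

validate_dce_plane <- function(x) {
  stopifnot(inherits(x, "dce_plane"))
  d <- dim(x$frames)
  if (length(x$timestamps) != d[1])
    stop(sprintf("timestamps length (%d) != number of frames (%d)",
                 length(x$timestamps), d[1]))
  if (any(diff(x$timestamps) <= 0))
    stop("timestamps must be strictly increasing")
  if (any(x$frames < 0, na.rm = TRUE))
    stop("frames must be non-negative after linearization")
  if (any(x$pixel_spacing <= 0)) stop("pixel_spacing must be > 0")
  invisible(x)
}

frame_shape <- function(dce) dim(dce$frames)[2:3]

#' Construct a co-registered plane bundle
#'
#' One imaging plane of one patient with all modalities on a common pixel
#' grid: the DCE-US loop, the B-mode gray-level image, the shear-wave
#' Young's-modulus map, the prostate mask, the PZ/TZ zone labels, a
#' calcification mask, and the histopathology-derived benign/malignant
#' regions of interest.
#'
#' @param dce A [dce_plane()].
#' @param bmode Numeric matrix, B-mode gray level (houses the `G` feature).
#' @param swe Numeric matrix, Young's modulus in kPa (houses `E`).
#' @param prostate_mask Logical matrix.
#' @param zone_mask Integer matrix with codes 0 = outside, 1 = PZ, 2 = TZ.
#' @param calcification_mask Logical matrix (may be all-`FALSE`).
#' @param roi_labels Integer matrix with codes 0 = unlabeled, 1 = benign,
#'   2 = malignant.
#' @return An object of class `plane_bundle`.
#' @export
plane_bundle <- function(dce, bmode, swe, prostate_mask, zone_mask,
                         calcification_mask = NULL, roi_labels = NULL) {
  shp <- frame_shape(dce)
  if (is.null(calcification_mask))
    calcification_mask <- matrix(FALSE, shp[1], shp[2])
  if (is.null(roi_labels))
    roi_labels <- matrix(ROI_UNLABELED, shp[1], shp[2])
  x <- structure(
    list(dce = dce, bmode = bmode, swe = swe,
         prostate_mask = prostate_mask,
         zone_mask = matrix(as.integer(zone_mask), nrow(zone_mask)),
         calcification_mask = calcification_mask,
         roi_labels = matrix(as.integer(roi_labels), nrow(roi_labels))),
    class = "plane_bundle")
  validate_plane_bundle(x)
}

validate_plane_bundle <- function(x) {
  stopifnot(inherits(x, "plane_bundle"))
  validate_dce_plane(x$dce)
  shp <- frame_shape(x$dce)
  rasters <- list(bmode = x$bmode, swe = x$swe,
                  prostate_mask = x$prostate_mask, zone_mask = x$zone_mask,
                  calcification_mask = x$calcification_mask,
                  roi_labels = x$roi_labels)
  for (nm in names(rasters)) {
    d <- dim(rasters[[nm]])
    if (is.null(d) || any(d != shp))
      stop(sprintf("raster '%s' shape (%s) does not match DCE frame shape (%s)",
                   nm, paste(d, collapse = "x"), paste(shp, collapse = "x")))
  }
  if (!is.logical(x$prostate_mask) || !is.logical(x$calcification_mask))
    stop("prostate_mask and calcification_mask must be logical")
  inside <- x$prostate_mask
  if (any(!(x$zone_mask[inside] %in% c(ZONE_PZ, ZONE_TZ))))
    stop("zone_mask must be PZ or TZ at every prostate pixel")
  if (any(x$zone_mask[!inside] != ZONE_OUTSIDE))
    stop("zone_mask carries a zone label outside the prostate mask")
  if (!all(x$roi_labels %in% c(ROI_UNLABELED, ROI_BENIGN, ROI_MALIGNANT)))
    stop("roi_labels must use codes 0 (unlabeled) / 1 (benign) / 2 (malignant)")
  if (any(x$roi_labels[!inside] != ROI_UNLABELED))
    stop("ROI-labeled pixels must lie inside the prostate mask")
  invisible(x)
}

#' Construct a named parametric map
#'
#' A per-pixel 2-D feature map with a validity mask. Pixels where
#' estimation failed are carried as `NA` (never silently zero) and are
#' excluded from medians, entropies and training downstream.
#'
#' @param name Feature identifier (a [param_catalog()] name or a radiomic
#'   derivative such as `"v.ent2"`).
#' @param values Numeric matrix; `NA` where invalid.
#' @param valid Logical matrix; defaults to `!is.na(values)`.
#' @param units Unit string.
#' @return An object of class `param_map`.
#' @export
param_map <- function(name, values, valid = NULL, units = "") {
  if (is.null(valid)) valid <- !is.na(values)
  stopifnot(identical(dim(values), dim(valid)))
  values[!valid] <- NA_real_
  structure(list(name = name, values = values, valid = valid, units = units),
            class = "param_map")
}

#' Linearize log-compressed ultrasound intensities
#'
#' Display-mode DCE-US data are log-compressed; model-based fitting needs
#' linear amplitudes. For 8-bit data `x` in 0..255 and a dynamic range
#' `DR` in dB, the linear amplitude is `10^(x * DR / (255 * 10))`, so
#' `x = 0` maps to 1 (the bottom of the scale) and `x = 255` to
#' `10^(DR/10)`.
#'
#' @param x Log-compressed values (any numeric array).
#' @param dynamic_range_db Dynamic range in dB (> 0).
#' @return Linear-scale values with the shape of `x`.
#' @seealso [compress_intensity()] for the inverse.
#' @export
linearize_intensity <- function(x, dynamic_range_db = 40) {
  if (dynamic_range_db <= 0) stop("dynamic_range_db must be > 0")
  10^(x * dynamic_range_db / (255 * 10))
}

#' @rdname linearize_intensity
#' @param y Linear-scale values (> 0).
#' @export
compress_intensity <- function(y, dynamic_range_db = 40) {
  if (dynamic_range_db <= 0) stop("dynamic_range_db must be > 0")
  255 * 10 * log10(y) / dynamic_range_db
}

#' Construct a per-pixel feature table
#'
#' Rows of labeled pixels feeding the zonal forest. Bookkeeping columns
#' (`patient_id`, `plane_id`, `row`, `col`, `zone`, `label`, `calcified`)
#' precede the feature columns, whose order is fixed by the manifest so
#' tables from different patients are guaranteed to align.
#'
#' @param df Data frame containing the bookkeeping columns and one column
#'   per manifest feature.
#' @param manifest Character vector of feature column names, in order.
#' @return A `feature_table` (a data frame with a `manifest` attribute).
#' @export
feature_table <- function(df, manifest = feature_manifest()) {
  required <- c("patient_id", "plane_id", "row", "col", "zone", "label",
                "calcified")
  missing_book <- setdiff(required, names(df))
  if (length(missing_book))
    stop("feature table lacks bookkeeping columns: ",
         paste(missing_book, collapse = ", "))
  missing_feat <- setdiff(manifest, names(df))
  if (length(missing_feat))
    stop("feature table lacks manifest columns: ",
         paste(head(missing_feat, 5), collapse = ", "))
  if (!all(df$label %in% c("benign", "malignant")))
    stop("labels must be 'benign' or 'malignant'")
  if (!all(df$zone %in% c("PZ", "TZ")))
    stop("no feature row may lie outside the prostate zones")
  df <- df[c(required, manifest)]
  structure(df, manifest = manifest,
            class = c("feature_table", "data.frame"))
}

#' @rdname feature_table
#' @param x Object to inspect.
#' @export
ft_manifest <- function(x) attr(x, "manifest")

# Feature columns as a numeric matrix.
ft_matrix <- function(x) {
  as.matrix(as.data.frame(x)[, ft_manifest(x), drop = FALSE])
}

zone_name <- function(code) c("PZ", "TZ")[match(code, c(ZONE_PZ, ZONE_TZ))]
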