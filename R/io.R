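# Readers/writers for plane bundles and feature tables.
#
# Rasters are persisted either as TIFF (primary interchange format;
# 32-bit float pages rescaled into [0, 1] with the affine scale recorded
# in the YAML sidecar) or as NIfTI (64-bit float, exact round trip).
# Masks are written as 8-bit label images with the code tables
# {0 outside, 1 PZ, 2 TZ}, {0/1 boolean} and {0 unlabeled, 1 benign,
# 2 malignant}.

RASTER_ROLES <- c("dce", "bmode", "swe", "prostate_mask", "zone_mask",
                  "calcification_mask", "roi_labels")

write_raster_tiff <- function(x, path, integer_codes = FALSE) {
  if (integer_codes) {
    pages <- if (length(dim(x)) == 3) {
      lapply(seq_len(dim(x)[1]), function(i) x[i, , ] / 255)
    } else list(x / 255)
    tiff::writeTIFF(pages, path, bits.per.sample = 8L)
    return(list(scale = 255, offset = 0))
  }
  lo <- min(x, na.rm = TRUE)
  hi <- max(x, na.rm = TRUE)
  scale <- if (hi > lo) hi - lo else 1
  xn <- (x - lo) / scale
  pages <- if (length(dim(x)) == 3) {
    lapply(seq_len(dim(x)[1]), function(i) xn[i, , ])
  } else list(xn)
  tiff::writeTIFF(pages, path, bits.per.sample = 32L, reduce = FALSE)
  list(scale = scale, offset = lo)
}

read_raster_tiff <- function(path, meta, integer_codes = FALSE) {
  pages <- tiff::readTIFF(path, all = TRUE)
  arr <- if (length(pages) == 1) pages[[1]] * meta$scale + meta$offset else {
    out <- array(0, c(length(pages), dim(pages[[1]])))
    for (i in seq_along(pages)) out[i, , ] <- pages[[i]] * meta$scale + meta$offset
    out
  }
  if (integer_codes) arr <- round(arr)
  arr
}

write_raster_nifti <- function(x, path) {
  # store frames as (row, col, time) volumes
  arr <- if (length(dim(x)) == 3) aperm(x, c(2, 3, 1)) else x
  RNifti::writeNifti(RNifti::asNifti(arr, datatype = "double"), path)
  list(scale = 1, offset = 0)
}

read_raster_nifti <- function(path, three_d = FALSE) {
  arr <- as.array(RNifti::readNifti(path))
  if (three_d) aperm(arr, c(3, 1, 2)) else arr[, , drop = TRUE]
}

#' Write and load a plane bundle on disk
#'
#' `write_plane_bundle()` lays a bundle out as one directory holding a
#' `meta.yaml` sidecar (identifiers, pixel spacing, timestamps, raster
#' scale factors) plus one image file per role. `load_plane_bundle()`
#' reads it back and re-validates every invariant; a missing file fails
#' naming the missing role, and a grid mismatch fails listing the shapes
#' rather than resampling silently.
#'
#' @param bundle A [plane_bundle()].
#' @param dir Directory to create/read.
#' @param format `"tiff"` (primary; 32-bit float, ~1e-7 relative fidelity)
#'   or `"nifti"` (64-bit float, exact).
#' @param log_compressed If `TRUE`, the stored DCE frames are 8-bit
#'   log-compressed and are linearized on load using
#'   `config$dynamic_range_db`.
#' @param config Optional [run_config()].
#' @return `load_plane_bundle()` returns a validated [plane_bundle()].
#' @export
write_plane_bundle <- function(bundle, dir, format = c("tiff", "nifti")) {
  format <- match.arg(format)
  validate_plane_bundle(bundle)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  ext <- if (format == "tiff") ".tif" else ".nii.gz"
  rasters <- list(
    dce = bundle$dce$frames, bmode = bundle$bmode, swe = bundle$swe,
    prostate_mask = bundle$prostate_mask * 1L,
    zone_mask = bundle$zone_mask,
    calcification_mask = bundle$calcification_mask * 1L,
    roi_labels = bundle$roi_labels)
  integer_roles <- c("prostate_mask", "zone_mask", "calcification_mask",
                     "roi_labels")
  scales <- list()
  for (role in RASTER_ROLES) {
    path <- file.path(dir, paste0(role, ext))
    scales[[role]] <- if (format == "tiff") {
      write_raster_tiff(rasters[[role]], path,
                        integer_codes = role %in% integer_roles)
    } else write_raster_nifti(rasters[[role]], path)
  }
  meta <- list(patient_id = bundle$dce$patient_id,
               plane_id = bundle$dce$plane_id,
               pixel_spacing = as.numeric(bundle$dce$pixel_spacing),
               timestamps = as.numeric(bundle$dce$timestamps),
               format = format,
               scales = scales)
  yaml::write_yaml(meta, file.path(dir, "meta.yaml"))
  invisible(dir)
}

#' @rdname write_plane_bundle
#' @export
load_plane_bundle <- function(dir, config = NULL, log_compressed = FALSE) {
  config <- as_run_config(config)
  meta_path <- file.path(dir, "meta.yaml")
  if (!file.exists(meta_path))
    stop("missing bundle sidecar: ", meta_path)
  meta <- yaml::read_yaml(meta_path)
  ext <- if (meta$format == "tiff") ".tif" else ".nii.gz"
  integer_roles <- c("prostate_mask", "zone_mask", "calcification_mask",
                     "roi_labels")
  rasters <- list()
  for (role in RASTER_ROLES) {
    path <- file.path(dir, paste0(role, ext))
    if (!file.exists(path))
      stop(sprintf("missing image for role '%s': %s", role, path))
    rasters[[role]] <- if (meta$format == "tiff") {
      read_raster_tiff(path, meta$scales[[role]],
                       integer_codes = role %in% integer_roles)
    } else read_raster_nifti(path, three_d = role == "dce")
  }
  frames <- rasters$dce
  if (log_compressed)
    frames <- linearize_intensity(frames, config$dynamic_range_db)
  dce <- dce_plane(frames, meta$timestamps, meta$pixel_spacing,
                   meta$patient_id, meta$plane_id)
  plane_bundle(dce, bmode = rasters$bmode, swe = rasters$swe,
               prostate_mask = rasters$prostate_mask > 0,
               zone_mask = rasters$zone_mask,
               calcification_mask = rasters$calcification_mask > 0,
               roi_labels = rasters$roi_labels)
}

#' Write and read a run configuration as YAML
#'
#' @param config A [run_config()].
#' @param path YAML file path.
#' @return `read_run_config()` returns a validated [run_config()].
#' @export
write_run_config <- function(config, path) {
  config <- as_run_config(config)
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' @rdname write_run_config
#' @export
read_run_config <- function(path) {
  vals <- yaml::read_yaml(path)
  do.call(run_config, vals)
}

#' Write and read a feature table as CSV
#'
#' The canonical on-disk form is CSV with a manifest line
#' (`#manifest: name1|name2|...`) preceding the header, so the feature
#' column order is explicit and is verified on read: a reordered or
#' renamed feature column fails loudly instead of silently misaligning
#' the classifier input.
#'
#' @param table A [feature_table()].
#' @param path CSV file path.
#' @return `read_feature_table()` returns a [feature_table()].
#' @export
write_feature_table <- function(table, path) {
  stopifnot(inherits(table, "feature_table"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("#manifest: ", paste(ft_manifest(table), collapse = "|")),
             con)
  write.csv(as.data.frame(table), con, row.names = FALSE)
  invisible(path)
}

#' @rdname write_feature_table
#' @export
read_feature_table <- function(path) {
  first <- readLines(path, n = 1)
  if (!startsWith(first, "#manifest: "))
    stop("feature table lacks a manifest line")
  manifest <- strsplit(sub("^#manifest: ", "", first), "|", fixed = TRUE)[[1]]
  df <- read.csv(path, skip = 1, stringsAsFactors = FALSE,
                 colClasses = c(patient_id = "character",
                                plane_id = "character"))
  feat_cols <- setdiff(names(df), c("patient_id", "plane_id", "row", "col",
                                    "zone", "label", "calcified"))
  if (!identical(feat_cols, manifest))
    stop("feature columns do not match the manifest (order or names differ)")
  if (nrow(df)) df$calcified <- as.logical(df$calcified)
  else df$calcified <- logical(0)
  feature_table(df, manifest)
}
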