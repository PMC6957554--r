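# End-to-end feature extraction: from a plane bundle to the 84-column
# per-pixel radiomic feature stack and the labeled feature table.

#' Extract all parametric maps and radiomic features of one plane
#'
#' Runs the full single-plane pipeline: optional motion compensation of
#' the loop, the bolus-model maps (`mu`, `kappa`, `alpha`, `AT`, `PT`,
#' `PI`, `WIT`), the dispersion maps (`v`, `D`, `Pe`, `r`, `rho`), the
#' `E` (Young's modulus) and `G` (gray level) maps, and the 84-column
#' radiomic expansion over the prostate mask.
#'
#' @param bundle A [plane_bundle()].
#' @param config Optional [run_config()].
#' @param motion_compensate If `TRUE`, the loop is rigidly stabilized
#'   first (slower; simulated bundles are static by default).
#' @param refine_vd Passed to [dispersion_maps()].
#' @return List with `maps` (14 base [param_map()]s), `features`
#'   ([radiomic_expand()] output), `calcifications` (detected mask) and
#'   the bundle identifiers.
#' @export
extract_plane_features <- function(bundle, config = NULL,
                                   motion_compensate = FALSE,
                                   refine_vd = TRUE) {
  config <- as_run_config(config)
  validate_plane_bundle(bundle)
  dce <- bundle$dce
  if (motion_compensate) dce <- compensate_motion(dce, config)
  mask <- bundle$prostate_mask
  sp <- dce$pixel_spacing
  maps <- tic_maps(dce, mask, config)
  maps <- c(maps, dispersion_maps(dce, mask, config, refine = refine_vd))
  vE <- bundle$swe; vE[!mask] <- NA
  vG <- bundle$bmode; vG[!mask] <- NA
  maps$E <- param_map("E", vE, units = "kPa")
  maps$G <- param_map("G", vG, units = "a.u.")
  maps <- maps[param_catalog()]
  features <- radiomic_expand(maps, mask, sp, config)
  calc <- detect_calcifications(bundle$bmode, mask, sp, config)
  list(maps = maps, features = features, calcifications = calc,
       patient_id = dce$patient_id, plane_id = dce$plane_id,
       bundle = bundle)
}

#' Extract features for every plane of a cohort
#'
#' @param cohort An `mpus_cohort`.
#' @param config Optional [run_config()].
#' @param progress Print per-plane progress.
#' @inheritParams extract_plane_features
#' @return List of per-plane records (see [extract_plane_features()]).
#' @export
cohort_features <- function(cohort, config = NULL,
                            motion_compensate = FALSE, refine_vd = TRUE,
                            progress = FALSE) {
  config <- as_run_config(config)
  planes <- list()
  for (p in cohort$patients) {
    for (pl_name in names(p$bundles)) {
      if (progress)
        message("extracting ", p$patient_id, "/", pl_name)
      planes[[paste(p$patient_id, pl_name, sep = "/")]] <-
        extract_plane_features(p$bundles[[pl_name]], config,
                               motion_compensate, refine_vd)
    }
  }
  planes
}

#' Build the labeled feature table from extracted planes
#'
#' Collects the ROI-labeled pixels of every plane into one
#' [feature_table()]. Pixels inside the bundle's calcification mask are
#' flagged `calcified` so training can omit them.
#'
#' @param planes Output of [cohort_features()].
#' @return A [feature_table()].
#' @export
build_feature_table <- function(planes) {
  rows <- list()
  for (pl in planes) {
    b <- pl$bundle
    idx <- pl$features$idx
    lab_code <- b$roi_labels[idx]
    sel <- lab_code != ROI_UNLABELED
    if (!any(sel)) next
    nr <- nrow(b$roi_labels)
    lin <- idx[sel]
    df <- data.frame(
      patient_id = pl$patient_id,
      plane_id = pl$plane_id,
      row = ((lin - 1) %% nr) + 1,
      col = ((lin - 1) %/% nr) + 1,
      zone = zone_name(b$zone_mask[lin]),
      label = c("benign", "malignant")[lab_code[sel]],
      calcified = b$calcification_mask[lin],
      stringsAsFactors = FALSE)
    df <- cbind(df, as.data.frame(pl$features$features[sel, , drop = FALSE]))
    rows[[length(rows) + 1]] <- df
  }
  if (!length(rows)) stop("no labeled pixels in any plane")
  feature_table(do.call(rbind, rows))
}
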