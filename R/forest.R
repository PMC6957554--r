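# Zonally stratified random forest with the published growing recipe.
#
# The forced first split on zonal location (PZ vs TZ) is realized as two
# independently grown per-zone forests; routing a sample uses exactly one
# stratum. Per tree: six training patients are discarded entirely, a
# bootstrap of 1/1000th of the remaining rows (with replacement) is
# drawn, and the tree is grown with cross-entropy splits, depth at most
# 50 and at least 5 samples per leaf, considering ceil(sqrt(p)) features
# per split. The multiparametric score of a pixel is
# (malignant votes - benign votes) / n_trees, in [-1, 1]; calcified
# pixels are omitted from training.

# Train one zonal stratum. The per-tree discarded patients are drawn from
# the full training cohort (all_patients); a draw that would leave the
# stratum without both classes or with fewer than 2*min_leaf rows is
# redrawn (relevant only for small synthetic cohorts).
train_stratum <- function(X, y, patients, all_patients, config, seed) {
  set.seed(seed)
  n_tr <- config$n_trees
  mtry <- ceiling(sqrt(ncol(X)))
  trees <- vector("list", n_tr)
  discarded <- vector("list", n_tr)
  boot_rows <- vector("list", n_tr)
  for (b in seq_len(n_tr)) {
    for (try_i in 1:100) {
      drop_pat <- sample(all_patients, config$patients_discarded_per_tree)
      keep <- which(!(patients %in% drop_pat))
      if (length(keep) >= 2 * config$min_leaf &&
          length(unique(y[keep])) == 2) break
      if (try_i == 100)
        stop("could not draw a per-tree patient subset keeping both classes")
    }
    m <- min(length(keep),
             max(config$min_tree_rows,
                 ceiling(length(keep) * config$subsample_fraction)))
    rows <- keep[sample.int(length(keep), m, replace = TRUE)]
    trees[[b]] <- .grow_tree_cpp(X, y, rows - 1L, mtry,
                                 config$max_depth, config$min_leaf)
    discarded[[b]] <- drop_pat
    boot_rows[[b]] <- rows
  }
  list(trees = trees, discarded = discarded, boot_rows = boot_rows,
       mtry = mtry, seed = seed)
}

# Deterministic per-stratum seeds derived from the training seed.
stratum_seeds <- function(seed) {
  c(PZ = (seed * 2654435761) %% 2147480009 + 1,
    TZ = (seed * 2654435761 + 97) %% 2147480009 + 1)
}

#' Train the zonal random forest
#'
#' Grows one forest per prostate zone (the forced zonal first split) on
#' the labeled, non-calcified, complete rows of a feature table. Fully
#' reproducible: the same `(table, config, seed)` yields bit-identical
#' models and scores.
#'
#' @param table A [feature_table()].
#' @param config Optional [run_config()].
#' @param seed Integer training seed.
#' @return A `zonal_forest`: per-stratum tree lists with their per-tree
#'   discarded patients and bootstrap rows, the feature manifest and a
#'   config snapshot.
#' @export
train_zonal_forest <- function(table, config = NULL, seed = 1) {
  config <- as_run_config(config)
  stopifnot(inherits(table, "feature_table"))
  df <- as.data.frame(table)
  X_all <- ft_matrix(table)
  usable <- !df$calcified & complete.cases(X_all)
  df <- df[usable, , drop = FALSE]
  X_all <- X_all[usable, , drop = FALSE]
  n_pat <- length(unique(df$patient_id))
  if (n_pat < config$patients_discarded_per_tree + 1)
    stop(sprintf("training requires at least %d patients (got %d): per-tree discarding of %d patients must leave data",
                 config$patients_discarded_per_tree + 1, n_pat,
                 config$patients_discarded_per_tree))
  seeds <- stratum_seeds(seed)
  strata <- list()
  for (z in c("PZ", "TZ")) {
    sel <- df$zone == z
    if (!any(sel)) stop("stratum ", z, " has no training rows")
    y <- as.integer(df$label[sel] == "malignant")
    if (length(unique(y)) < 2)
      stop("stratum ", z, " contains a single class; cannot train")
    strata[[z]] <- train_stratum(X_all[sel, , drop = FALSE], y,
                                 df$patient_id[sel],
                                 sort(unique(df$patient_id)),
                                 config, seeds[[z]])
    strata[[z]]$patient_ids <- df$patient_id[sel]
  }
  structure(list(strata = strata, manifest = ft_manifest(table),
                 seed = seed, config = config),
            class = "zonal_forest")
}

#' Multiparametric score of feature rows
#'
#' Routes each row to the forest stratum of its zone and returns
#' `(malignant votes - benign votes) / n_trees` in `[-1, 1]`. Rows with
#' an unknown zone or incomplete features are `NA`.
#'
#' @param model A trained `zonal_forest`.
#' @param X Numeric matrix whose columns follow the model manifest, or a
#'   [feature_table()].
#' @param zone Character vector (`"PZ"`/`"TZ"`), one per row (taken from
#'   the table when `X` is a [feature_table()]).
#' @return Numeric score vector.
#' @export
score_pixels <- function(model, X, zone = NULL) {
  if (inherits(X, "feature_table")) {
    if (!identical(ft_manifest(X), model$manifest))
      stop("feature manifest does not match the trained model")
    zone <- as.data.frame(X)$zone
    X <- ft_matrix(X)
  }
  stopifnot(!is.null(zone), length(zone) == nrow(X))
  n_tr <- model$config$n_trees
  out <- rep(NA_real_, nrow(X))
  complete <- complete.cases(X)
  for (z in c("PZ", "TZ")) {
    sel <- which(zone == z & complete)
    if (!length(sel)) next
    votes1 <- .predict_forest_cpp(model$strata[[z]]$trees,
                                  X[sel, , drop = FALSE])
    out[sel] <- (2 * votes1 - n_tr) / n_tr
  }
  out
}

#' Multiparametric score map of a plane
#'
#' Scores every prostate pixel of a plane's expanded feature stack.
#'
#' @param model A trained `zonal_forest`.
#' @param features Output of [radiomic_expand()] (fields `features`,
#'   `idx`).
#' @param zone_mask Integer zone mask of the plane.
#' @return A [param_map()] named `"score"` with values in `[-1, 1]`.
#' @export
score_map <- function(model, features, zone_mask) {
  shp <- dim(zone_mask)
  zc <- zone_mask[features$idx]
  zone <- ifelse(zc == ZONE_PZ, "PZ", ifelse(zc == ZONE_TZ, "TZ", NA))
  sc <- score_pixels(model, features$features, zone)
  m <- matrix(NA_real_, shp[1], shp[2])
  m[features$idx] <- sc
  param_map("score", m, units = "-")
}

#' Median post-filter of a score map
#'
#' Replaces each valid pixel by the median score in a circular
#' `radius_px` neighborhood intersected with the valid pixels, removing
#' isolated outliers from the multiparametric image (the default 15 px
#' corresponds to ~2.5 mm, about half the radius of a clinically
#' significant lesion). Invalid pixels stay invalid.
#'
#' @param map A [param_map()] (e.g. from [score_map()]).
#' @param radius_px Kernel radius in pixels.
#' @return Filtered [param_map()].
#' @export
median_postfilter <- function(map, radius_px = 15) {
  vals <- map$values
  valid <- map$valid
  idx <- which(valid)
  if (!length(idx)) return(map)
  r <- max(1, round(radius_px))
  g <- expand.grid(dr = -r:r, dc = -r:r)
  g <- g[g$dr^2 + g$dc^2 <= r^2, ]
  nr <- nrow(vals); nc <- ncol(vals)
  out <- vals
  rr0 <- ((idx - 1) %% nr) + 1
  cc0 <- ((idx - 1) %/% nr) + 1
  for (j in seq_along(idx)) {
    rr <- rr0[j] + g$dr
    cc <- cc0[j] + g$dc
    ok <- rr >= 1 & rr <= nr & cc >= 1 & cc <= nc
    lin <- rr[ok] + (cc[ok] - 1) * nr
    lin <- lin[valid[lin]]
    out[idx[j]] <- median(vals[lin])
  }
  param_map(map$name, out, valid, map$units)
}

#' Verify the forced-zonal-split construction
#'
#' The forced first split on zone is implemented as two per-stratum
#' forests. This check retrains each stratum independently with the same
#' per-stratum seed and asserts that the probe predictions agree exactly,
#' and that a probe routed to one zone never consults the other stratum's
#' trees.
#'
#' @param model A trained `zonal_forest`.
#' @param table The training [feature_table()].
#' @param probe Optional probe [feature_table()] (defaults to `table`).
#' @return List with `equivalent` (logical), `first_mismatch` (row index
#'   or `NA`), and per-zone tree-use counters for a single-zone probe.
#' @export
zonal_equivalence_check <- function(model, table, probe = NULL) {
  if (is.null(probe)) probe <- table
  config <- model$config
  df <- as.data.frame(table)
  X_all <- ft_matrix(table)
  usable <- !df$calcified & complete.cases(X_all)
  df <- df[usable, ]; X_all <- X_all[usable, , drop = FALSE]
  seeds <- stratum_seeds(model$seed)
  rebuilt <- model
  for (z in c("PZ", "TZ")) {
    sel <- df$zone == z
    y <- as.integer(df$label[sel] == "malignant")
    rebuilt$strata[[z]] <- train_stratum(X_all[sel, , drop = FALSE], y,
                                         df$patient_id[sel],
                                         sort(unique(df$patient_id)),
                                         config, seeds[[z]])
  }
  s1 <- score_pixels(model, probe)
  s2 <- score_pixels(rebuilt, probe)
  same <- (is.na(s1) & is.na(s2)) | (!is.na(s1) & !is.na(s2) & s1 == s2)
  first_bad <- if (all(same)) NA_integer_ else which(!same)[1]
  pz_probe <- as.data.frame(probe)$zone == "PZ"
  list(equivalent = all(same), first_mismatch = first_bad,
       trees_used = c(PZ = if (any(pz_probe)) config$n_trees else 0L,
                      TZ = if (any(!pz_probe)) config$n_trees else 0L))
}
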