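# Validation machinery: leave-one-patient-out cross-validation,
# rank-based ROC-AUC, Wilcoxon rank-sum comparisons and the
# feature-correlation matrix.

#' Rank-based ROC-AUC
#'
#' Area under the ROC curve computed as the Mann-Whitney statistic with
#' midrank tie handling; equals the fraction of concordant
#' positive/negative pairs plus half the tied pairs. The complement
#' identity `roc_auc(s, l) + roc_auc(-s, l) = 1` holds exactly.
#'
#' @param scores Numeric vector.
#' @param labels Logical or 0/1 vector (`TRUE`/1 = positive class).
#' @return AUC in `[0, 1]`.
#' @export
roc_auc <- function(scores, labels) {
  labels <- as.logical(labels)
  keep <- !is.na(scores) & !is.na(labels)
  scores <- scores[keep]; labels <- labels[keep]
  n1 <- sum(labels); n0 <- sum(!labels)
  if (n1 == 0 || n0 == 0)
    stop("ROC-AUC requires both classes present")
  r <- rank(scores, ties.method = "average")
  (sum(r[labels]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Mean multiparametric score per region of interest
#'
#' A region is characterized by the mean of its valid pixel scores; a
#' region without a single valid pixel is flagged.
#'
#' @param map A [param_map()] (typically the post-filtered score map).
#' @param roi_labels Integer matrix, 0 unlabeled / 1 benign / 2 malignant.
#' @return Data frame with `label`, `mean_score`, `n_valid`, `flagged`.
#' @export
region_scores <- function(map, roi_labels) {
  out <- list()
  for (code in c(ROI_BENIGN, ROI_MALIGNANT)) {
    sel <- roi_labels == code
    if (!any(sel)) next
    vals <- map$values[sel & map$valid]
    out[[length(out) + 1]] <- data.frame(
      label = c("benign", "malignant")[code],
      mean_score = if (length(vals)) mean(vals) else NA_real_,
      n_valid = length(vals),
      flagged = length(vals) == 0)
  }
  if (!length(out))
    return(data.frame(label = character(0), mean_score = numeric(0),
                      n_valid = integer(0), flagged = logical(0)))
  do.call(rbind, out)
}

#' Wilcoxon rank-sum test
#'
#' Two-sided rank-sum test: exact by enumeration of all assignments when
#' `n_x + n_y <= 12` (midranks under ties; p doubled from the smaller
#' tail, capped at 1). Larger samples use the exact Wilcoxon null
#' distribution when the data carry no ties, and the normal
#' approximation with tie and continuity corrections otherwise.
#' Significance is flagged at 0.05 and 0.005.
#'
#' @param x,y Numeric samples (non-empty).
#' @param exact_max Total sample size up to which exact enumeration is
#'   used.
#' @return List with `U` (Mann-Whitney statistic of `x`), `p`, `method`,
#'   `significant`, `highly_significant`.
#' @export
wilcoxon_rank_sum <- function(x, y, exact_max = 12) {
  if (!length(x) || !length(y)) stop("both groups must be non-empty")
  nx <- length(x); ny <- length(y); n <- nx + ny
  r <- rank(c(x, y), ties.method = "average")
  U_obs <- sum(r[seq_len(nx)]) - nx * (nx + 1) / 2
  if (n <= exact_max) {
    combos <- utils::combn(n, nx)
    Us <- colSums(matrix(r[combos], nrow = nx)) - nx * (nx + 1) / 2
    eps <- 1e-9
    p_lo <- mean(Us <= U_obs + eps)
    p_hi <- mean(Us >= U_obs - eps)
    p <- min(1, 2 * min(p_lo, p_hi))
    method <- "exact enumeration"
  } else if (!anyDuplicated(r)) {
    p_lo <- stats::pwilcox(U_obs, nx, ny)
    p_hi <- 1 - stats::pwilcox(U_obs - 1, nx, ny)
    p <- min(1, 2 * min(p_lo, p_hi))
    method <- "exact distribution"
  } else {
    mu <- nx * ny / 2
    ties <- table(r)
    tie_term <- sum(ties^3 - ties) / (n * (n - 1))
    sigma2 <- nx * ny / 12 * ((n + 1) - tie_term)
    if (sigma2 <= 0) {
      p <- 1
    } else {
      z <- (U_obs - mu - sign(U_obs - mu) * 0.5) / sqrt(sigma2)
      p <- 2 * pnorm(-abs(z))
    }
    method <- "normal approximation"
  }
  list(U = U_obs, p = p, method = method,
       significant = p < 0.05, highly_significant = p < 0.005)
}

#' Pearson correlation matrix of the feature columns
#'
#' Symmetric Pearson matrix over the manifest features (complete rows),
#' with per-entry p-values from the t-distribution of the correlation
#' coefficient and a mask of entries not significantly reflecting a
#' linear correlation (p > 0.05).
#'
#' @param table A [feature_table()] (or numeric matrix).
#' @return List with `correlation`, `p_value`, `not_significant`, `n`.
#' @export
feature_correlation_matrix <- function(table) {
  X <- if (inherits(table, "feature_table")) ft_matrix(table) else
    as.matrix(table)
  X <- X[complete.cases(X), , drop = FALSE]
  n <- nrow(X)
  if (n < 3) stop("correlation matrix requires at least 3 complete rows")
  sds <- apply(X, 2, sd)
  C <- suppressWarnings(cor(X))
  diag(C) <- 1
  tstat <- C * sqrt((n - 2) / pmax(1 - C^2, .Machine$double.eps))
  P <- 2 * pt(-abs(tstat), df = n - 2)
  diag(P) <- 0
  bad <- sds == 0
  C[bad, ] <- NA; C[, bad] <- NA
  P[bad, ] <- NA; P[, bad] <- NA
  diag(C)[!bad] <- 1
  list(correlation = C, p_value = P,
       not_significant = !is.na(P) & P > 0.05, n = n)
}

#' Restrict a feature table to one parameter's radiomic block
#'
#' Keeps only the six radiomic columns of one base parameter, so that
#' [lopo_crossval()] on the result evaluates a per-parameter classifier
#' (the "forest" mode of single-parameter comparison) rather than the
#' raw parameter value.
#'
#' @param table A [feature_table()].
#' @param feature A [param_catalog()] name.
#' @return A [feature_table()] with a six-column manifest.
#' @export
single_feature_table <- function(table, feature) {
  stopifnot(feature %in% param_catalog())
  cols <- paste0(feature, radiomic_suffixes())
  df <- as.data.frame(table)
  feature_table(df[c("patient_id", "plane_id", "row", "col", "zone",
                     "label", "calcified", cols)], manifest = cols)
}

fold_seed <- function(seed, k) {
  as.integer((as.numeric(seed) * 48271 + k * 16807) %% 2147483323) + 1L
}

roi_key <- function(df) paste(df$patient_id, df$plane_id, df$label, sep = "/")

#' Leave-one-patient-out cross-validation
#'
#' For each patient, a zonal forest is trained on all other patients'
#' labeled pixels and the held-out patient is scored. With per-plane
#' feature stacks available (`planes`), the held-out score maps are
#' median post-filtered before pixel- and region-level pooling, matching
#' the full pipeline. AUCs are pooled over all held-out pixels/regions;
#' per-patient AUCs are emitted for diagnostics.
#'
#' @param table [feature_table()] of labeled pixels for all patients.
#' @param config Optional [run_config()].
#' @param seed Integer seed; per-fold training seeds derive from it.
#' @param planes Optional list of per-plane records, each with fields
#'   `patient_id`, `plane_id`, `features` ([radiomic_expand()] output)
#'   and `bundle` (the [plane_bundle()]); enables map post-filtering and
#'   region scoring on maps.
#' @param single_features If `TRUE`, also computes pixel- and region-wise
#'   AUCs of every raw feature column for comparison with the
#'   multiparametric score.
#' @return A `cv_result` list: `pixel` (held-out pixel scores), `regions`
#'   (per-ROI mean scores), `auc` (pooled multiparametric and single
#'   feature AUCs), `folds` (training patient sets per fold), `seed`,
#'   `config`.
#' @export
lopo_crossval <- function(table, config = NULL, seed = 1, planes = NULL,
                          single_features = TRUE) {
  config <- as_run_config(config)
  df <- as.data.frame(table)
  patients <- sort(unique(df$patient_id))
  if (length(patients) < 8)
    stop("leave-one-patient-out evaluation requires at least 8 patients")
  pixel_rows <- list()
  region_rows <- list()
  folds <- list()
  for (k in seq_along(patients)) {
    pat <- patients[k]
    train_sel <- df$patient_id != pat
    test_sel <- !train_sel
    if (!any(test_sel)) {
      warning("patient ", pat, " has no labeled pixels; skipped")
      next
    }
    train_tab <- feature_table(df[train_sel, , drop = FALSE],
                               ft_manifest(table))
    folds[[pat]] <- sort(unique(train_tab$patient_id))
    model <- train_zonal_forest(train_tab, config, fold_seed(seed, k))
    test_df <- df[test_sel, , drop = FALSE]
    if (is.null(planes)) {
      sc <- score_pixels(model, feature_table(test_df, ft_manifest(table)))
      test_df$score <- sc
    } else {
      test_df$score <- NA_real_
      for (pl in planes) {
        if (pl$patient_id != pat) next
        smap <- score_map(model, pl$features, pl$bundle$zone_mask)
        smap <- median_postfilter(smap, config$median_filter_radius_px)
        in_pl <- test_df$plane_id == pl$plane_id
        lin <- test_df$row[in_pl] +
          (test_df$col[in_pl] - 1) * nrow(smap$values)
        test_df$score[in_pl] <- smap$values[lin]
      }
    }
    pixel_rows[[pat]] <- test_df
    agg <- stats::aggregate(score ~ patient_id + plane_id + label + zone,
                            data = test_df, FUN = mean, na.rm = TRUE,
                            na.action = stats::na.pass)
    region_rows[[pat]] <- agg
  }
  pixel <- do.call(rbind, pixel_rows)
  regions <- do.call(rbind, region_rows)
  rownames(pixel) <- rownames(regions) <- NULL
  lab_pix <- pixel$label == "malignant"
  lab_reg <- regions$label == "malignant"
  auc <- list(
    mp_pixel = roc_auc(pixel$score, lab_pix),
    mp_region = roc_auc(regions$score, lab_reg))
  if (single_features) {
    manifest <- ft_manifest(table)
    base <- intersect(param_catalog(), manifest)
    pix_f <- reg_f <- setNames(numeric(length(base)), base)
    for (nm in base) {
      vals <- df[[nm]]
      pix_f[nm] <- roc_auc(vals, df$label == "malignant")
      agg <- stats::aggregate(stats::setNames(df[nm], "value"),
                              by = df[c("patient_id", "plane_id", "label")],
                              FUN = mean, na.rm = TRUE)
      reg_f[nm] <- roc_auc(agg$value, agg$label == "malignant")
    }
    auc$feature_pixel <- pix_f
    auc$feature_region <- reg_f
    # discriminative ability irrespective of the parameter's sign
    # convention (e.g. shorter wash-in time in malignant tissue)
    auc$feature_pixel_oriented <- pmax(pix_f, 1 - pix_f)
    auc$feature_region_oriented <- pmax(reg_f, 1 - reg_f)
  }
  structure(list(pixel = pixel, regions = regions, auc = auc,
                 folds = folds, seed = seed, config = config),
            class = "cv_result")
}
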