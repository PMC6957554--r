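# Radiomic derivatives of parametric maps and calcification detection.
#
# Each base map contributes its value, the value relative to the in-mask
# median (intra-prostate asymmetry), local Shannon entropy of the value
# distribution in circular kernels of ~1, ~2 and ~3 mm (heterogeneity at
# three scales), and the local variance in a ~2-mm kernel (granularity).
# Kernels are specified in mm and converted to pixels via the plane's
# pixel spacing, rounding the radius to the nearest pixel (at least 1).

# Integer offsets of a circular kernel of physical radius radius_mm,
# excluding the center pixel.
circular_offsets <- function(radius_mm, pixel_spacing, include_center = TRUE) {
  if (length(pixel_spacing) == 1) pixel_spacing <- rep(pixel_spacing, 2)
  r_px <- max(1, round(radius_mm / mean(pixel_spacing)))
  g <- expand.grid(dr = -r_px:r_px, dc = -r_px:r_px)
  keep <- g$dr^2 + g$dc^2 <= r_px^2
  if (!include_center) keep <- keep & !(g$dr == 0 & g$dc == 0)
  g[keep, , drop = FALSE]
}

#' Parameter value relative to the per-image median
#'
#' Subtracts the median of the valid in-mask values from every pixel, so
#' the output quantifies intra-prostate asymmetry independently of the
#' patient-level parameter magnitude. The in-mask median of the result is
#' exactly zero. A difference (rather than a ratio) is used because
#' several maps legitimately take zero or negative values.
#'
#' @param map A [param_map()].
#' @param prostate_mask Logical matrix.
#' @param mode `"difference"` (default) or `"ratio"` (strictly positive
#'   maps only).
#' @return A [param_map()] named `<name>.rel`.
#' @export
relative_to_median <- function(map, prostate_mask, mode = c("difference",
                                                            "ratio")) {
  mode <- match.arg(mode)
  sel <- map$valid & prostate_mask
  nm <- paste0(map$name, ".rel")
  if (!any(sel))
    return(param_map(nm, matrix(NA_real_, nrow(map$values), ncol(map$values)),
                     units = map$units))
  med <- median(map$values[sel])
  vals <- if (mode == "difference") map$values - med else {
    if (med <= 0) stop("ratio mode requires a strictly positive median")
    map$values / med
  }
  vals[!sel] <- NA_real_
  param_map(nm, vals, units = if (mode == "difference") map$units else "-")
}

# Per-offset neighborhood accumulation over the valid pixels of a map.
# Returns per-center member count and, if values given, running sums; if
# bins given, per-bin counts. Centers are the pixels listed in idx.
neighborhood_accumulate <- function(mask_valid, idx, offsets, values = NULL,
                                    bin_assign = NULL, n_bins = NULL) {
  np <- length(idx)
  cnt <- numeric(np)
  s1 <- s2 <- if (!is.null(values)) numeric(np) else NULL
  counts <- if (!is.null(bin_assign)) matrix(0L, np, n_bins) else NULL
  for (k in seq_len(nrow(offsets))) {
    q <- offset_neighbor_cols(mask_valid, idx, offsets$dr[k], offsets$dc[k])
    ok <- !is.na(q)
    if (!any(ok)) next
    cnt[ok] <- cnt[ok] + 1
    if (!is.null(values)) {
      vq <- values[q[ok]]
      s1[ok] <- s1[ok] + vq
      s2[ok] <- s2[ok] + vq^2
    }
    if (!is.null(bin_assign)) {
      ij <- cbind(which(ok), bin_assign[q[ok]])
      counts[ij] <- counts[ij] + 1L
    }
  }
  list(count = cnt, s1 = s1, s2 = s2, counts = counts)
}

#' Local entropy of a parametric map
#'
#' Shannon entropy (bits) of the histogram of valid map values inside a
#' circular kernel around each pixel. Bin edges are computed once per
#' image over the robust (1st-99th percentile) range of the valid in-mask
#' values; values outside the range are clamped into the boundary bins.
#' Pixels with fewer than `min_members` valid kernel members, or with an
#' invalid base value, are invalid.
#'
#' @param map A [param_map()].
#' @param radius_mm Kernel radius (mm).
#' @param pixel_spacing mm/px `(row, col)`.
#' @param config Optional [run_config()] (`entropy_bins`).
#' @param min_members Minimum valid kernel members (default 10).
#' @param name Output map name; defaults to `<name>.ent<radius>`.
#' @return A [param_map()] of entropies in bits.
#' @export
local_entropy <- function(map, radius_mm, pixel_spacing, config = NULL,
                          min_members = 10, name = NULL) {
  config <- as_run_config(config)
  if (is.null(name)) name <- paste0(map$name, ".ent", round(radius_mm))
  d <- dim(map$values)
  out <- matrix(NA_real_, d[1], d[2])
  sel <- map$valid
  idx <- which(sel)
  if (!length(idx)) return(param_map(name, out, units = "bit"))
  x <- map$values[idx]
  rng <- quantile(x, c(0.01, 0.99), names = FALSE, type = 7)
  nb <- config$entropy_bins
  if (rng[2] > rng[1]) {
    edges <- seq(rng[1], rng[2], length.out = nb + 1)
    bin <- pmin(pmax(findInterval(x, edges, rightmost.closed = TRUE), 1), nb)
  } else bin <- rep(1L, length(x))
  offs <- circular_offsets(radius_mm, pixel_spacing)
  acc <- neighborhood_accumulate(sel, idx, offs, bin_assign = bin,
                                 n_bins = nb)
  n <- acc$count
  P <- acc$counts / pmax(n, 1)
  lp <- ifelse(P > 0, P * log2(P), 0)
  ent <- -rowSums(lp)
  good <- n >= min_members
  out[idx[good]] <- ent[good]
  param_map(name, out, units = "bit")
}

#' Local variance of a parametric map
#'
#' Unbiased sample variance of the valid map values inside a circular
#' kernel (default ~2 mm). Pixels with fewer than 2 valid members, or
#' with an invalid base value, are invalid.
#'
#' @inheritParams local_entropy
#' @param radius_mm Kernel radius (mm), default 2.
#' @return A [param_map()] named `<name>.var2` by default.
#' @export
local_variance <- function(map, radius_mm = 2, pixel_spacing, config = NULL,
                           name = NULL) {
  if (is.null(name)) name <- paste0(map$name, ".var", round(radius_mm))
  d <- dim(map$values)
  out <- matrix(NA_real_, d[1], d[2])
  sel <- map$valid
  idx <- which(sel)
  if (!length(idx)) return(param_map(name, out, units = map$units))
  offs <- circular_offsets(radius_mm, pixel_spacing)
  acc <- neighborhood_accumulate(sel, idx, offs, values = map$values[idx])
  n <- acc$count
  good <- n >= 2
  v <- (acc$s2 - acc$s1^2 / pmax(n, 1)) / pmax(n - 1, 1)
  v <- pmax(v, 0)
  out[idx[good]] <- v[good]
  param_map(name, out, units = map$units)
}

# Separable Gaussian smoothing with edge replication.
gaussian_smooth <- function(x, sigma_px) {
  half <- max(1, ceiling(4 * sigma_px))
  k <- exp(-0.5 * ((-half:half) / sigma_px)^2)
  k <- k / sum(k)
  smooth_axis <- function(m) {
    top <- m[rep(1, half), , drop = FALSE]
    bot <- m[rep(nrow(m), half), , drop = FALSE]
    padded <- rbind(top, m, bot)
    f <- stats::filter(padded, k, sides = 2)
    matrix(f[(half + 1):(half + nrow(m)), ], nrow(m), ncol(m))
  }
  t(smooth_axis(t(smooth_axis(x))))
}

# Connected-component labeling (4-connectivity) for small binary masks.
label_components <- function(mask) {
  lab <- matrix(0L, nrow(mask), ncol(mask))
  nr <- nrow(mask)
  current <- 0L
  todo <- which(mask)
  for (p in todo) {
    if (lab[p] != 0L) next
    current <- current + 1L
    frontier <- p
    lab[p] <- current
    while (length(frontier)) {
      r <- ((frontier - 1) %% nr) + 1
      cands <- c(frontier[r > 1] - 1, frontier[r < nr] + 1,
                 frontier - nr, frontier + nr)
      cands <- cands[cands >= 1 & cands <= length(mask)]
      cands <- unique(cands[mask[cands] & lab[cands] == 0L])
      lab[cands] <- current
      frontier <- cands
    }
  }
  lab
}

#' Detect calcifications in a B-mode image
#'
#' Calcifications appear as hyperechoic (bright) spots; they are found by
#' convolving the B-mode image with two Gaussian kernels (sigma ~0.6 mm
#' and ~1.8 mm, matched to spots of roughly 1.2 and 3.6 mm diameter),
#' thresholding each response `calc_k` standard deviations above the
#' center of the in-mask response (estimated robustly as median +
#' `calc_k` * 1.4826 * MAD, so the calcifications themselves cannot
#' inflate the threshold), taking the union of the two binarized
#' responses, and discarding connected components smaller than
#' `calc_min_px` pixels. Detected pixels are excluded from
#' classifier training because their elevated stiffness and echogenicity
#' obscure the underlying tissue.
#'
#' @param bmode Numeric matrix (gray level) or a [param_map()].
#' @param prostate_mask Logical matrix.
#' @param pixel_spacing mm/px `(row, col)`.
#' @param config Optional [run_config()].
#' @return Logical matrix, `TRUE` at detected calcification pixels.
#' @export
detect_calcifications <- function(bmode, prostate_mask, pixel_spacing,
                                  config = NULL) {
  config <- as_run_config(config)
  if (inherits(bmode, "param_map")) bmode <- bmode$values
  if (length(pixel_spacing) == 1) pixel_spacing <- rep(pixel_spacing, 2)
  det <- matrix(FALSE, nrow(bmode), ncol(bmode))
  robust_thr <- function(vals) {
    scale <- stats::mad(vals)
    if (!is.finite(scale) || scale == 0) return(Inf)
    median(vals) + config$calc_k * scale
  }
  for (sig_mm in config$calc_sigmas_mm) {
    resp <- gaussian_smooth(bmode, sig_mm / mean(pixel_spacing))
    rin <- resp[prostate_mask]
    if (!length(rin)) next
    # robust center/scale so the calcifications themselves cannot inflate
    # the threshold
    det <- det | (resp > robust_thr(rin) & prostate_mask)
  }
  # the matched-filter response spills beyond a bright spot; keep only
  # pixels that are themselves hyperechoic in the raw image
  if (any(prostate_mask))
    det <- det & bmode > robust_thr(bmode[prostate_mask])
  if (any(det)) {
    lab <- label_components(det)
    sizes <- tabulate(lab)
    small <- which(sizes < config$calc_min_px)
    if (length(small)) det[lab %in% small] <- FALSE
  }
  det
}

#' Expand base maps into the full radiomic feature set
#'
#' For each of the 14 base maps (in [param_catalog()] order) computes the
#' 6 radiomic derivatives (value, relative-to-median, entropy at 3
#' scales, 2-mm variance), yielding the 84 manifest-ordered per-pixel
#' feature columns over the prostate mask. An invalid base pixel
#' propagates invalidity to all its derivatives; the input order of
#' `maps` never affects the output (columns follow the manifest).
#'
#' @param maps Named list containing one [param_map()] per catalog name.
#' @param prostate_mask Logical matrix.
#' @param pixel_spacing mm/px `(row, col)`.
#' @param config Optional [run_config()].
#' @return List with `features` (n_prostate_px x 84 matrix, `NA` where
#'   invalid), `manifest`, and `idx` (linear pixel indices of the rows).
#' @export
radiomic_expand <- function(maps, prostate_mask, pixel_spacing,
                            config = NULL) {
  config <- as_run_config(config)
  cat_names <- param_catalog()
  missing_maps <- setdiff(cat_names, names(maps))
  if (length(missing_maps))
    stop("missing base maps: ", paste(missing_maps, collapse = ", "))
  shp <- dim(prostate_mask)
  for (nm in cat_names) {
    if (!identical(dim(maps[[nm]]$values), shp))
      stop(sprintf("map '%s' grid (%s) does not match mask grid (%s)", nm,
                   paste(dim(maps[[nm]]$values), collapse = "x"),
                   paste(shp, collapse = "x")))
  }
  idx <- which(prostate_mask)
  manifest <- feature_manifest()
  features <- matrix(NA_real_, length(idx), length(manifest),
                     dimnames = list(NULL, manifest))
  radii <- config$entropy_radii_mm
  for (nm in cat_names) {
    base <- maps[[nm]]
    base$valid <- base$valid & prostate_mask
    base$values[!base$valid] <- NA_real_
    derivs <- list(base, relative_to_median(base, prostate_mask))
    for (j in seq_along(radii)) {
      derivs[[length(derivs) + 1]] <-
        local_entropy(base, radii[j], pixel_spacing, config,
                      name = paste0(nm, ".ent", j))
    }
    derivs[[length(derivs) + 1]] <-
      local_variance(base, config$variance_radius_mm, pixel_spacing,
                     config, name = paste0(nm, ".var2"))
    cols <- paste0(nm, radiomic_suffixes())
    for (k in seq_along(cols))
      features[, cols[k]] <- derivs[[k]]$values[idx]
  }
  list(features = features, manifest = manifest, idx = idx)
}
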