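# Rigid motion compensation of DCE-US cine loops.
#
# The loop is registered to its wash-in reference frame (the frame closest
# to 30 s): transforms are estimated at every 5th frame by maximizing
# normalized cross-correlation over translation and rotation
# (coarse-to-fine; FFT correlation for the shift, golden-section for the
# angle), and intermediate frames are warped with componentwise linearly
# interpolated (tx, ty, theta).

#' Index of the wash-in reference frame
#'
#' The prostate position during wash-in (at 30 s after injection) anchors
#' all registration; this returns the index of the frame whose timestamp
#' is nearest 30 s, ties resolved toward the earlier frame.
#'
#' @param dce A [dce_plane()].
#' @param reference_s Reference time in seconds (default 30).
#' @return Integer frame index.
#' @export
estimate_reference_frame <- function(dce, reference_s = 30) {
  t <- dce$timestamps
  if (max(t) < reference_s)
    stop(sprintf("loop ends at %.1f s; a %.0f-s reference requires a longer recording",
                 max(t), reference_s))
  d <- abs(t - reference_s)
  which(d == min(d))[1]
}

# Bilinear rigid resampling: out(u) = img(R(u - c) + c + t), zero fill.
rigid_warp <- function(img, tx_px = 0, ty_px = 0, rot_deg = 0) {
  if (tx_px == 0 && ty_px == 0 && rot_deg == 0) return(img)
  nr <- nrow(img); nc <- ncol(img)
  cr <- (nr + 1) / 2; cc <- (nc + 1) / 2
  th <- rot_deg * pi / 180
  co <- cos(th); si <- sin(th)
  r <- matrix(seq_len(nr), nr, nc) - cr
  c2 <- matrix(seq_len(nc), nr, nc, byrow = TRUE) - cc
  sr <- co * r - si * c2 + cr + ty_px
  sc <- si * r + co * c2 + cc + tx_px
  r0 <- floor(sr); c0 <- floor(sc)
  fr <- sr - r0; fc <- sc - c0
  ok <- r0 >= 1 & r0 <= nr - 1 & c0 >= 1 & c0 <= nc - 1
  out <- matrix(0, nr, nc)
  i00 <- cbind(r0[ok], c0[ok])
  out[ok] <-
    img[i00] * (1 - fr[ok]) * (1 - fc[ok]) +
    img[cbind(r0[ok] + 1, c0[ok])] * fr[ok] * (1 - fc[ok]) +
    img[cbind(r0[ok], c0[ok] + 1)] * (1 - fr[ok]) * fc[ok] +
    img[cbind(r0[ok] + 1, c0[ok] + 1)] * fr[ok] * fc[ok]
  out
}

#' Apply a rigid transform to a frame
#'
#' @param img Numeric matrix.
#' @param transform A `rigid_transform` (see [estimate_rigid()]).
#' @param pixel_spacing mm/px `(row, col)` used to convert the stored
#'   mm translation back to pixels.
#' @return Warped matrix (bilinear interpolation, zero fill).
#' @export
apply_rigid <- function(img, transform, pixel_spacing) {
  if (length(pixel_spacing) == 1) pixel_spacing <- rep(pixel_spacing, 2)
  rigid_warp(img,
             tx_px = transform$translation_mm[2] / pixel_spacing[2],
             ty_px = transform$translation_mm[1] / pixel_spacing[1],
             rot_deg = transform$rotation_deg)
}

# FFT cross-correlation of zero-mean images; returns the integer shift
# (moving sampled at u + s matches reference) with subpixel parabolic
# refinement, restricted to |s| <= max_shift.
xcorr_shift <- function(reference, moving, max_shift) {
  nr <- nrow(reference); nc <- ncol(reference)
  pr <- stats::nextn(nr + 2 * ceiling(max_shift), 2)
  pc <- stats::nextn(nc + 2 * ceiling(max_shift), 2)
  R <- matrix(0, pr, pc); M <- matrix(0, pr, pc)
  R[1:nr, 1:nc] <- reference - mean(reference)
  M[1:nr, 1:nc] <- moving - mean(moving)
  cc <- Re(fft(fft(M) * Conj(fft(R)), inverse = TRUE)) / (pr * pc)
  sh <- ceiling(max_shift)
  idx_r <- c(pr - sh + seq_len(sh), 1:(sh + 1))   # shifts -sh..sh
  idx_c <- c(pc - sh + seq_len(sh), 1:(sh + 1))
  win <- cc[idx_r, idx_c]
  best <- which(win == max(win), arr.ind = TRUE)[1, ]
  par_refine <- function(m, i, j) {
    d <- c(0, 0)
    if (i > 1 && i < nrow(m)) {
      den <- m[i - 1, j] - 2 * m[i, j] + m[i + 1, j]
      if (den < 0) d[1] <- 0.5 * (m[i - 1, j] - m[i + 1, j]) / den
    }
    if (j > 1 && j < ncol(m)) {
      den <- m[i, j - 1] - 2 * m[i, j] + m[i, j + 1]
      if (den < 0) d[2] <- 0.5 * (m[i, j - 1] - m[i, j + 1]) / den
    }
    d
  }
  dd <- par_refine(win, best[1], best[2])
  s_row <- (best[1] - sh - 1) + dd[1]
  s_col <- (best[2] - sh - 1) + dd[2]
  norm <- sqrt(sum(R^2) * sum(M^2))
  list(s_row = s_row, s_col = s_col,
       score = if (norm > 0) max(win) / norm else 0)
}

#' Estimate the rigid transform aligning a frame to a reference
#'
#' Maximizes intensity cross-correlation over translation (within
#' `max_shift_mm`) and rotation about the image center (within
#' `max_rot_deg`): a coarse rotation grid with FFT translation search,
#' followed by golden-section refinement of the angle and parabolic
#' subpixel refinement of the shift. A flat (zero-variance) frame cannot
#' be registered and yields the identity with `flat = TRUE`.
#'
#' @param moving,reference Numeric matrices of identical shape.
#' @param pixel_spacing mm/px `(row, col)`.
#' @param max_shift_mm,max_rot_deg Search bounds.
#' @param rot_step_deg Coarse rotation grid step.
#' @return A `rigid_transform`: list with `translation_mm` (row, col),
#'   `rotation_deg`, `score`, `flat`.
#' @export
estimate_rigid <- function(moving, reference, pixel_spacing,
                           max_shift_mm = 5, max_rot_deg = 10,
                           rot_step_deg = 2) {
  if (!identical(dim(moving), dim(reference)))
    stop("frames must share one shape")
  if (length(pixel_spacing) == 1) pixel_spacing <- rep(pixel_spacing, 2)
  identity_tf <- list(translation_mm = c(0, 0), rotation_deg = 0,
                      score = NA_real_, flat = FALSE)
  class(identity_tf) <- "rigid_transform"
  if (sd(moving) == 0 || sd(reference) == 0) {
    identity_tf$flat <- TRUE
    warning("flat frame: returning identity transform")
    return(identity_tf)
  }
  max_shift_px <- max(max_shift_mm / pixel_spacing)
  eval_theta <- function(theta) {
    m_rot <- rigid_warp(moving, 0, 0, theta)
    xcorr_shift(reference, m_rot, max_shift_px)
  }
  thetas <- seq(-max_rot_deg, max_rot_deg, by = rot_step_deg)
  scores <- lapply(thetas, eval_theta)
  best_i <- which.max(vapply(scores, `[[`, 0, "score"))
  lo <- max(-max_rot_deg, thetas[best_i] - rot_step_deg)
  hi <- min(max_rot_deg, thetas[best_i] + rot_step_deg)
  gold <- (sqrt(5) - 1) / 2
  a <- lo; b <- hi
  x1 <- b - gold * (b - a); x2 <- a + gold * (b - a)
  f1 <- eval_theta(x1)$score; f2 <- eval_theta(x2)$score
  while (b - a > 0.05) {
    if (f1 < f2) {
      a <- x1; x1 <- x2; f1 <- f2
      x2 <- a + gold * (b - a); f2 <- eval_theta(x2)$score
    } else {
      b <- x2; x2 <- x1; f2 <- f1
      x1 <- b - gold * (b - a); f1 <- eval_theta(x1)$score
    }
  }
  theta <- (a + b) / 2
  fit <- eval_theta(theta)
  # shift s found on the rotated frame corresponds to translation t = R s
  th <- theta * pi / 180
  t_row <- cos(th) * fit$s_row - sin(th) * fit$s_col
  t_col <- sin(th) * fit$s_row + cos(th) * fit$s_col
  out <- list(translation_mm = c(t_row * pixel_spacing[1],
                                 t_col * pixel_spacing[2]),
              rotation_deg = theta, score = fit$score, flat = FALSE)
  class(out) <- "rigid_transform"
  out
}

#' Motion-compensate a DCE-US loop
#'
#' Rigid transforms are estimated at every 5th frame (anchored at the
#' wash-in reference frame and extending in both directions); intermediate
#' frames receive componentwise linear interpolation of (tx, ty, theta)
#' between their bracketing anchors, and frames beyond the outermost
#' anchors reuse the nearest anchor's transform. Frames whose registration
#' score falls below `min_score` keep the identity (uninformative
#' pre-arrival frames carry no registrable structure).
#'
#' @param dce A [dce_plane()] (at least 6 frames).
#' @param config Optional [run_config()].
#' @param anchor_stride Frames between registration anchors (default 5).
#' @param min_score Correlation floor below which an anchor falls back to
#'   the identity transform.
#' @param reference_s Reference timestamp in seconds.
#' @return A [dce_plane()] of compensated frames; the per-frame transform
#'   table (columns `frame`, `tx_mm`, `ty_mm`, `rot_deg`, `anchor`) is
#'   attached as attribute `"transforms"`.
#' @export
compensate_motion <- function(dce, config = NULL, anchor_stride = 5,
                              min_score = 0.1, reference_s = 30) {
  validate_dce_plane(dce)
  n <- dim(dce$frames)[1]
  if (n < 6) stop("motion compensation requires at least 6 frames")
  ref_idx <- estimate_reference_frame(dce, reference_s)
  reference <- dce$frames[ref_idx, , ]
  anchors <- sort(unique(c(seq(ref_idx, 1, by = -anchor_stride),
                           seq(ref_idx, n, by = anchor_stride))))
  sp <- dce$pixel_spacing
  apar <- matrix(0, length(anchors), 3)  # ty_px, tx_px, theta
  for (k in seq_along(anchors)) {
    i <- anchors[k]
    if (i == ref_idx) next
    tf <- suppressWarnings(
      estimate_rigid(dce$frames[i, , ], reference, sp))
    if (tf$flat || is.na(tf$score) || tf$score < min_score) next
    est <- c(tf$translation_mm[1] / sp[1],
             tf$translation_mm[2] / sp[2],
             tf$rotation_deg)
    # snap below the estimator noise floor so static loops pass unchanged
    est[abs(est) < 0.05] <- 0
    apar[k, ] <- est
  }
  # interpolate componentwise between anchors
  interp <- apply(apar, 2, function(v)
    stats::approx(anchors, v, xout = seq_len(n), rule = 2)$y)
  out <- dce$frames
  for (i in seq_len(n)) {
    out[i, , ] <- rigid_warp(dce$frames[i, , ],
                             tx_px = interp[i, 2], ty_px = interp[i, 1],
                             rot_deg = interp[i, 3])
  }
  res <- dce_plane(out, dce$timestamps, sp, dce$patient_id, dce$plane_id)
  attr(res, "transforms") <- data.frame(
    frame = seq_len(n),
    tx_mm = interp[, 2] * sp[2], ty_mm = interp[, 1] * sp[1],
    rot_deg = interp[, 3], anchor = seq_len(n) %in% anchors)
  res
}
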