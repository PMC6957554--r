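# Neighborhood dispersion and perfusion estimators (CUDI).
#
# Contrast transport through the microvasculature is treated as a
# convective-dispersive process. Around each pixel a ring kernel selects
# neighbors at microvascular distances; the similarity of their contrast
# kinetics is summarized by spatiotemporal correlation (r) and spectral
# coherence (rho), while local system identification estimates the
# convective velocity v (mm/s) and dispersion D (mm^2/s) by deconvolving
# the center-to-neighbor impulse response and fitting the 1-D
# convection-dispersion Green's function
#   g(t; d, v, D) = d / sqrt(4*pi*D*t^3) * exp(-(d - v*t)^2 / (4*D*t)),
# jointly across neighbors. The Peclet number is Pe = v*L/D with L the
# mean neighbor distance.

#' Ring kernel of neighbor offsets
#'
#' Integer pixel offsets whose physical distance from the center lies in
#' `[inner_mm, outer_mm]`. Beyond `max_members` the members are decimated
#' uniformly in angle, which preserves the isotropy of the ring.
#'
#' @param pixel_spacing mm/px `(row, col)`.
#' @param inner_mm,outer_mm Ring bounds (mm), `0 < inner < outer`.
#' @param max_members Optional cap on the number of members.
#' @return Data frame with `dr`, `dc`, `dist_mm`, `angle`.
#' @export
ring_kernel <- function(pixel_spacing, inner_mm = 0.5, outer_mm = 2.0,
                        max_members = Inf) {
  if (length(pixel_spacing) == 1) pixel_spacing <- rep(pixel_spacing, 2)
  if (inner_mm <= 0 || outer_mm <= inner_mm)
    stop("ring kernel requires 0 < inner < outer")
  rmax <- ceiling(outer_mm / min(pixel_spacing))
  g <- expand.grid(dr = -rmax:rmax, dc = -rmax:rmax)
  d <- sqrt((g$dr * pixel_spacing[1])^2 + (g$dc * pixel_spacing[2])^2)
  keep <- d >= inner_mm & d <= outer_mm
  g <- g[keep, ]; d <- d[keep]
  ang <- atan2(g$dr, g$dc)
  o <- order(ang, d)
  g <- g[o, ]; d <- d[o]; ang <- ang[o]
  if (nrow(g) > max_members) {
    pick <- unique(round(seq(1, nrow(g), length.out = max_members)))
    g <- g[pick, ]; d <- d[pick]; ang <- ang[pick]
  }
  data.frame(dr = g$dr, dc = g$dc, dist_mm = d, angle = ang,
             row.names = NULL)
}

#' Spatiotemporal correlation of a pixel with its ring neighbors
#'
#' Mean Pearson correlation between the center TIC and each neighbor TIC
#' over the bolus window (from 5 s before the center's appearance time to
#' 60 s after it, clipped to the record).
#'
#' @param center A preprocessed [tic()].
#' @param neighbors List of preprocessed [tic()]s on the same time base.
#' @param config Optional [run_config()].
#' @return Mean correlation in `[-1, 1]`, or `NA` for a zero-variance
#'   center.
#' @export
spatiotemporal_correlation <- function(center, neighbors, config = NULL) {
  config <- as_run_config(config)
  t <- center$t
  # offset-free copy so the bolus window is invariant to intensity offsets
  c0 <- center
  c0$y <- c0$y - min(c0$y)
  h <- heuristic_params(c0, config)
  w <- if (h$valid && !is.na(h$AT)) {
    t >= h$AT + config$corr_window_s[1] & t <= h$AT + config$corr_window_s[2]
  } else rep(TRUE, length(t))
  x <- center$y[w]
  if (sd(x) == 0) return(NA_real_)
  vals <- vapply(neighbors, function(nb) {
    y <- nb$y[w]
    if (sd(y) == 0) return(NA_real_)
    cor(x, y)
  }, 0)
  mean(vals, na.rm = TRUE)
}

# Boxcar taper: segments are demeaned, and an untapered segment keeps
# the coherence of a delayed copy near unity, which tapers erode.
welch_taper <- function(n) rep(1, n)

# Welch segment layout for a record of n samples.
welch_segments <- function(n, seg_len) {
  step <- seg_len %/% 2
  starts <- seq(1, n - seg_len + 1, by = step)
  lapply(starts, function(s) s:(s + seg_len - 1))
}

# Band bin indices (excluding DC) for segment length L and sampling dt.
welch_band_bins <- function(seg_len, dt, band_hz) {
  f <- (seq_len(seg_len) - 1) / (seg_len * dt)
  which(f > max(band_hz[1], 1e-12) & f <= band_hz[2])
}

welch_msc_pair <- function(x, y, dt, config) {
  L <- config$coherence_segment
  segs <- welch_segments(length(x), L)
  win <- welch_taper(L)
  bins <- welch_band_bins(L, dt, config$coherence_band_hz)
  Sxx <- Syy <- numeric(L)
  Sxy <- complex(L)
  Sxy <- rep(0 + 0i, L)
  for (sg in segs) {
    xs <- x[sg] - mean(x[sg]); ys <- y[sg] - mean(y[sg])
    X <- fft(xs * win); Y <- fft(ys * win)
    Sxx <- Sxx + Mod(X)^2
    Syy <- Syy + Mod(Y)^2
    Sxy <- Sxy + X * Conj(Y)
  }
  num <- Mod(Sxy[bins])^2
  den <- Sxx[bins] * Syy[bins]
  ok <- den > 0
  if (!any(ok)) return(NA_real_)
  mean(num[ok] / den[ok])
}

#' Spectral coherence of a pixel with its ring neighbors
#'
#' Magnitude-squared coherence (Welch estimate: 32-sample segments, 50\%
#' overlap, per-segment demeaning, untapered) averaged over the
#' sub-0.5 Hz bolus band and then over the neighbors. Coherence is
#' invariant to delays between center and neighbor, which makes it a pure
#' dispersion measure.
#'
#' @inheritParams spatiotemporal_correlation
#' @return Mean coherence in `[0, 1]`, `NA` for zero-variance input.
#' @export
spectral_coherence <- function(center, neighbors, config = NULL) {
  config <- as_run_config(config)
  if (length(center$t) < 64)
    stop("spectral coherence requires at least 64 samples")
  dt <- mean(diff(center$t))
  if (sd(center$y) == 0) return(NA_real_)
  vals <- vapply(neighbors, function(nb) {
    if (sd(nb$y) == 0) return(NA_real_)
    welch_msc_pair(center$y, nb$y, dt, config)
  }, 0)
  mean(vals, na.rm = TRUE)
}

#' Convection-dispersion Green's function
#'
#' @param t Seconds (> 0; the function is 0 at `t <= 0`).
#' @param d Transport distance (mm).
#' @param v Convective velocity (mm/s).
#' @param D Dispersion coefficient (mm^2/s).
#' @return Impulse-response values.
#' @export
conv_disp_green <- function(t, d, v, D) {
  out <- numeric(length(t))
  pos <- t > 0
  tp <- t[pos]
  out[pos] <- d / sqrt(4 * pi * D * tp^3) * exp(-(d - v * tp)^2 / (4 * D * tp))
  out
}

# Tikhonov-regularized FFT deconvolution: impulse response of y given
# input x, on the first n_h samples; lambda is relative to mean |X|^2.
# Also returns the effective regularization filter B(f) = P/(P + lambda*mean(P)),
# with which the estimate relates to the true response as h_est = b (*) h_true:
# candidate models must be blurred by the same filter before comparison
# (reconvolution-space fitting), otherwise the regularization bias
# propagates into (v, D).
deconvolve_ir <- function(x, y, dt, lambda, n_h) {
  n <- length(x)
  nfft <- stats::nextn(2 * n, 2)
  X <- fft(c(x, rep(0, nfft - n)))
  Y <- fft(c(y, rep(0, nfft - n)))
  P <- Mod(X)^2
  B <- P / (P + lambda * mean(P))
  H <- Conj(X) * Y / (P + lambda * mean(P))
  h <- Re(fft(H, inverse = TRUE)) / nfft
  list(h = h[seq_len(n_h)] / dt, B = B, nfft = nfft)
}

# Blur model columns (n_h x K) with the regularization filter B.
blur_columns <- function(G, B, nfft) {
  n_h <- nrow(G)
  pad <- rbind(G, matrix(0, nfft - n_h, ncol(G)))
  Re(stats::mvfft(stats::mvfft(pad) * B, inverse = TRUE))[seq_len(n_h), ,
                                                          drop = FALSE] / nfft
}

# Profiled RSS for the joint Green's-function fit: h_mat (n_h x n_members)
# against s * b (*) g(t; d_k, v, D) with the scale s >= 0 profiled out.
conv_disp_rss <- function(log_vd, h_mat, d_mm, t_h, B = NULL, nfft = NULL) {
  v <- exp(log_vd[1]); D <- exp(log_vd[2])
  G <- vapply(d_mm, function(d) conv_disp_green(t_h, d, v, D),
              numeric(length(t_h)))
  if (!is.null(B)) G <- blur_columns(G, B, nfft)
  num <- sum(h_mat * G)
  den <- sum(G^2)
  s <- if (den > 0) max(num / den, 0) else 0
  sum((h_mat - s * G)^2)
}

fit_conv_disp <- function(h_mat, d_mm, t_h,
                          v_bounds = c(0.02, 10), D_bounds = c(1e-3, 5),
                          grid_init = NULL, B = NULL, nfft = NULL) {
  if (is.null(grid_init)) {
    vg <- exp(seq(log(v_bounds[1] * 1.5), log(v_bounds[2] / 1.5),
                  length.out = 20))
    Dg <- exp(seq(log(D_bounds[1] * 1.5), log(D_bounds[2] / 1.5),
                  length.out = 12))
    grid <- as.matrix(expand.grid(v = vg, D = Dg))
    rss <- apply(grid, 1, function(p)
      conv_disp_rss(log(p), h_mat, d_mm, t_h, B, nfft))
    grid_init <- grid[which.min(rss), ]
  }
  res <- optim(log(grid_init), conv_disp_rss,
               h_mat = h_mat, d_mm = d_mm, t_h = t_h, B = B, nfft = nfft,
               method = "Nelder-Mead",
               control = list(maxit = 300, reltol = 1e-12))
  v <- exp(res$par[1]); D <- exp(res$par[2])
  eps <- 1.05
  at_bound <- v <= v_bounds[1] * eps || v >= v_bounds[2] / eps ||
    D <= D_bounds[1] * eps || D >= D_bounds[2] / eps
  list(v = unname(v), D = unname(D), rss = res$value,
       converged = res$convergence == 0 && !at_bound)
}

#' Local system identification of convection and dispersion
#'
#' Estimates the impulse response from the center TIC to each ring
#' neighbor by Tikhonov-regularized least-squares deconvolution, then fits
#' the convection-dispersion Green's function jointly across neighbors by
#' nonlinear least squares over `(v, D)` with a common profiled amplitude.
#'
#' @param center A preprocessed [tic()].
#' @param neighbors List of preprocessed [tic()]s.
#' @param distances_mm Physical center-to-neighbor distances (mm), one per
#'   neighbor.
#' @param config Optional [run_config()].
#' @param ir_horizon_s Length (s) of the impulse-response support kept for
#'   fitting.
#' @return A `conv_disp_estimate`: list with `v`, `D`, `Pe`, `L_mm`,
#'   `rss`, `valid`. The identity `Pe = v * L / D` holds exactly.
#' @export
identify_conv_disp <- function(center, neighbors, distances_mm,
                               config = NULL, ir_horizon_s = 30) {
  config <- as_run_config(config)
  if (length(neighbors) < 8)
    stop("local system identification requires at least 8 neighbors")
  stopifnot(length(neighbors) == length(distances_mm))
  bad <- structure(list(v = NA_real_, D = NA_real_, Pe = NA_real_,
                        L_mm = mean(distances_mm), rss = NA_real_,
                        valid = FALSE), class = "conv_disp_estimate")
  x <- center$y
  if (sd(x) == 0) return(bad)
  dt <- mean(diff(center$t))
  n_h <- min(length(x), round(ir_horizon_s / dt) + 1)
  t_h <- (seq_len(n_h) - 1) * dt
  dec <- lapply(neighbors, function(nb)
    deconvolve_ir(x, nb$y, dt, config$deconv_lambda, n_h))
  h_mat <- vapply(dec, `[[`, numeric(n_h), "h")
  fit <- fit_conv_disp(h_mat, distances_mm, t_h,
                       B = dec[[1]]$B, nfft = dec[[1]]$nfft)
  # transport faster than one sample interval over the nearest neighbor
  # is unresolvable (e.g. neighbors identical to the center)
  if (fit$converged && fit$v * dt >= min(distances_mm))
    fit$converged <- FALSE
  if (!fit$converged) return(bad)
  L <- mean(distances_mm)
  structure(list(v = fit$v, D = fit$D, Pe = fit$v * L / fit$D,
                 L_mm = L, rss = fit$rss, valid = TRUE),
            class = "conv_disp_estimate")
}

# Shift the column-index lookup of masked pixels by an offset: for each
# masked pixel (its position in idx), the column of its (dr, dc) neighbor
# in the masked matrix, or NA.
offset_neighbor_cols <- function(mask, idx, dr, dc) {
  nr <- nrow(mask); nc <- ncol(mask)
  lut <- matrix(0L, nr, nc)
  lut[idx] <- seq_along(idx)
  rr <- ((idx - 1) %% nr) + 1 + dr
  cc <- ((idx - 1) %/% nr) + 1 + dc
  ok <- rr >= 1 & rr <= nr & cc >= 1 & cc <= nc
  out <- rep(NA_integer_, length(idx))
  out[ok] <- lut[cbind(rr[ok], cc[ok])]
  out[!is.na(out) & out == 0] <- NA_integer_
  out
}

#' Per-pixel dispersion and perfusion maps
#'
#' Computes the `r`, `rho`, `v`, `D` and `Pe` maps over the prostate mask
#' using the ring kernel. Border pixels whose ring partially exits the
#' prostate use the available members if at least 8 remain, and are
#' invalid otherwise.
#'
#' @param dce A motion-compensated [dce_plane()].
#' @param prostate_mask Logical matrix.
#' @param config Optional [run_config()].
#' @param refine If `TRUE` (default) the per-pixel `(v, D)` grid solution
#'   is polished by Nelder-Mead; grid-only is faster and coarser.
#' @param ir_horizon_s Impulse-response support (s).
#' @return Named list of [param_map()]s (`v`, `D`, `Pe`, `r`, `rho`).
#' @export
dispersion_maps <- function(dce, prostate_mask, config = NULL,
                            refine = TRUE, ir_horizon_s = 30) {
  config <- as_run_config(config)
  shp <- frame_shape(dce)
  units <- param_units()
  empty <- function(nm) param_map(nm, matrix(NA_real_, shp[1], shp[2]),
                                  units = units[[nm]])
  out <- lapply(setNames(nm = c("v", "D", "Pe", "r", "rho")), empty)
  idx <- which(prostate_mask)
  if (!length(idx)) return(out)
  t <- dce$timestamps
  dt <- mean(diff(t))
  Y <- preprocess_matrix(tic_matrix(dce, prostate_mask), t, config)
  npx <- ncol(Y)
  ring <- ring_kernel(dce$pixel_spacing, config$ring_inner_mm,
                      config$ring_outer_mm, config$ring_max_members)
  n_off <- nrow(ring)
  nbr <- vapply(seq_len(n_off), function(k)
    offset_neighbor_cols(prostate_mask, idx, ring$dr[k], ring$dc[k]),
    integer(npx))
  if (npx == 1) nbr <- matrix(nbr, nrow = 1)
  member_ok <- !is.na(nbr)
  n_members <- rowSums(member_ok)
  sd0 <- apply(Y, 2, sd)
  enough <- n_members >= 8 & sd0 > 0

  ## --- spatiotemporal correlation ---------------------------------------
  h <- heuristics_matrix(Y, t, config)
  at <- ifelse(is.na(h$AT), t[1], h$AT)
  Tm <- matrix(t, nrow(Y), npx)
  W <- (Tm >= rep(at + config$corr_window_s[1], each = nrow(Y))) &
       (Tm <= rep(at + config$corr_window_s[2], each = nrow(Y)))
  Wn <- W * 1
  nW <- colSums(Wn)
  WX <- Y * Wn
  Sx <- colSums(WX); Sxx <- colSums(WX * Y)
  vx <- Sxx - Sx^2 / nW
  r_sum <- numeric(npx); r_cnt <- numeric(npx)
  for (k in seq_len(n_off)) {
    q <- nbr[, k]
    ok <- member_ok[, k]
    Yq <- Y[, ifelse(ok, q, 1), drop = FALSE]
    WYq <- Yq * Wn
    Sy <- colSums(WYq); Syy <- colSums(WYq * Yq)
    Sxy <- colSums(WX * Yq)
    vy <- Syy - Sy^2 / nW
    cov <- Sxy - Sx * Sy / nW
    good <- ok & vx > 0 & vy > 0
    r_sum[good] <- r_sum[good] + cov[good] / sqrt(vx[good] * vy[good])
    r_cnt[good] <- r_cnt[good] + 1
  }
  r_val <- ifelse(r_cnt > 0 & enough, r_sum / pmax(r_cnt, 1), NA_real_)

  ## --- spectral coherence -----------------------------------------------
  L <- config$coherence_segment
  rho_val <- rep(NA_real_, npx)
  if (nrow(Y) >= 64) {
    segs <- welch_segments(nrow(Y), L)
    win <- welch_taper(L)
    bins <- welch_band_bins(L, dt, config$coherence_band_hz)
    nb_bins <- length(bins)
    Xs <- vector("list", length(segs))
    Sxx_b <- matrix(0, nb_bins, npx)
    for (si in seq_along(segs)) {
      seg <- Y[segs[[si]], , drop = FALSE]
      seg <- sweep(seg, 2, colMeans(seg)) * win
      F <- stats::mvfft(seg)[bins, , drop = FALSE]
      if (nb_bins == 1) F <- matrix(F, 1)
      Xs[[si]] <- F
      Sxx_b <- Sxx_b + Mod(F)^2
    }
    rho_sum <- numeric(npx); rho_cnt <- numeric(npx)
    for (k in seq_len(n_off)) {
      q <- nbr[, k]; ok <- member_ok[, k]
      qi <- ifelse(ok, q, 1)
      Sxy_b <- matrix(0 + 0i, nb_bins, npx)
      for (si in seq_along(segs))
        Sxy_b <- Sxy_b + Xs[[si]] * Conj(Xs[[si]][, qi, drop = FALSE])
      Syy_b <- Sxx_b[, qi, drop = FALSE]
      den <- Sxx_b * Syy_b
      msc <- ifelse(den > 0, Mod(Sxy_b)^2 / den, NA)
      m <- colMeans(msc)
      good <- ok & !is.na(m)
      rho_sum[good] <- rho_sum[good] + m[good]
      rho_cnt[good] <- rho_cnt[good] + 1
    }
    rho_val <- ifelse(rho_cnt > 0 & enough, rho_sum / pmax(rho_cnt, 1),
                      NA_real_)
  }

  ## --- convection-dispersion identification -----------------------------
  n_h <- min(nrow(Y), round(ir_horizon_s / dt) + 1)
  t_h <- (seq_len(n_h) - 1) * dt
  nfft <- stats::nextn(nrow(Y) + 2 * n_h, 2)
  Fy <- stats::mvfft(rbind(Y, matrix(0, nfft - nrow(Y), npx)))
  P <- Mod(Fy)^2
  Pbar <- rowMeans(P)
  B_ref <- Pbar / (Pbar + config$deconv_lambda * mean(Pbar))
  denom <- P + config$deconv_lambda * rep(colMeans(P), each = nfft)
  # banded time-domain blur operator equivalent to the reference
  # regularization filter (truncated at +-taps samples)
  b_ker <- Re(fft(B_ref, inverse = TRUE)) / nfft
  taps <- min(64, nfft %/% 2 - 1)
  Tblur <- matrix(0, n_h, n_h)
  for (i in seq_len(n_h)) {
    j <- seq_len(n_h)
    lag <- i - j
    use <- abs(lag) <= taps
    Tblur[i, use] <- b_ker[(lag[use] %% nfft) + 1]
  }
  # shared blurred Green's-function library over a log (v, D) grid
  vg <- exp(seq(log(0.05), log(5), length.out = 20))
  Dg <- exp(seq(log(0.005), log(2), length.out = 12))
  grid <- as.matrix(expand.grid(v = vg, D = Dg))
  tp <- t_h[-1]
  off_rows <- rep(seq_len(n_off), each = n_h)
  green_library <- function(gridpts) {
    ng <- nrow(gridpts)
    out <- matrix(0, n_h * n_off, ng)
    Vm <- matrix(gridpts[, 1], length(tp), ng, byrow = TRUE)
    Dm <- matrix(gridpts[, 2], length(tp), ng, byrow = TRUE)
    Tm <- matrix(tp, length(tp), ng)
    for (oi in seq_len(n_off)) {
      d <- ring$dist_mm[oi]
      Gm <- d / sqrt(4 * pi * Dm * Tm^3) * exp(-(d - Vm * Tm)^2 / (4 * Dm * Tm))
      out[(oi - 1) * n_h + seq_len(n_h), ] <- Tblur %*% rbind(0, Gm)
    }
    out
  }
  score_chunk <- function(Hmat, ok_chunk, Gmat, ng) {
    G2 <- rowsum(Gmat^2, off_rows)
    Nmat <- crossprod(Hmat, Gmat)
    Dmat <- (ok_chunk * 1) %*% G2
    ifelse(Dmat > 0 & Nmat > 0, Nmat^2 / Dmat, -Inf)
  }
  Gcoarse <- green_library(grid)
  lstep_v <- diff(log(vg))[1]; lstep_D <- diff(log(Dg))[1]
  loc <- as.matrix(expand.grid(dv = seq(-1, 1, length.out = 5) * lstep_v,
                               dD = seq(-1, 1, length.out = 5) * lstep_D))
  v_val <- D_val <- pe_val <- rep(NA_real_, npx)
  L_pix <- as.vector((member_ok %*% ring$dist_mm)) / pmax(n_members, 1)
  chunk_size <- 1500
  for (ch_start in seq(1, npx, by = chunk_size)) {
    ch <- ch_start:min(ch_start + chunk_size - 1, npx)
    h_arr <- array(0, c(n_h, n_off, length(ch)))
    for (k in seq_len(n_off)) {
      q <- nbr[ch, k]; ok <- member_ok[ch, k]
      qi <- ifelse(ok, q, 1)
      H <- Conj(Fy[, ch, drop = FALSE]) * Fy[, qi, drop = FALSE] /
        denom[, ch, drop = FALSE]
      hk <- Re(stats::mvfft(H, inverse = TRUE))[seq_len(n_h), ,
                                                drop = FALSE] / (nfft * dt)
      hk[, !ok] <- 0
      h_arr[, k, ] <- hk
    }
    Hmat <- matrix(h_arr, n_h * n_off, length(ch))
    sc <- score_chunk(Hmat, member_ok[ch, , drop = FALSE], Gcoarse,
                      nrow(grid))
    usable <- enough[ch] & apply(sc, 1, max) > -Inf
    best <- max.col(sc, ties.method = "first")
    if (refine) {
      for (cell in unique(best[usable])) {
        sel <- which(usable & best == cell)
        if (!length(sel)) next
        lg <- cbind(exp(log(grid[cell, 1]) + loc[, 1]),
                    exp(log(grid[cell, 2]) + loc[, 2]))
        Gloc <- green_library(lg)
        scl <- score_chunk(Hmat[, sel, drop = FALSE],
                           member_ok[ch[sel], , drop = FALSE], Gloc,
                           nrow(lg))
        bl <- max.col(scl, ties.method = "first")
        v_val[ch[sel]] <- lg[bl, 1]
        D_val[ch[sel]] <- lg[bl, 2]
      }
    } else {
      v_val[ch[usable]] <- grid[best[usable], 1]
      D_val[ch[usable]] <- grid[best[usable], 2]
    }
  }
  # estimates pinned at the library edge, or faster than one sample
  # interval over the innermost ring distance, are not identified
  edge <- !is.na(v_val) &
    (v_val <= min(vg) * 1.01 | v_val >= max(vg) * 0.99 |
     D_val <= min(Dg) * 1.01 | D_val >= max(Dg) * 0.99 |
     v_val * dt >= min(ring$dist_mm))
  v_val[edge] <- D_val[edge] <- NA_real_
  pe_val <- v_val * L_pix / D_val

  fill <- function(nm, vals) {
    m <- matrix(NA_real_, shp[1], shp[2])
    m[idx] <- vals
    param_map(nm, m, units = units[[nm]])
  }
  out$r <- fill("r", r_val)
  out$rho <- fill("rho", rho_val)
  out$v <- fill("v", v_val)
  out$D <- fill("D", D_val)
  out$Pe <- fill("Pe", pe_val)
  out
}
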