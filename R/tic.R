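# Per-pixel time-intensity-curve (TIC) analysis.
#
# Contrast kinetics in one pixel are modeled by a modified local density
# random walk (LDRW) bolus model,
#   C(t) = alpha * sqrt(kappa / (2*pi*(t - t0))) *
#          exp(-kappa * (t - t0 - mu)^2 / (2*(t - t0)))   for t > t0,
# whose parameters are the area under the curve alpha (a.u.*s), the
# dispersion-related rate kappa (1/s) and the mean transit time mu (s),
# with t0 the arrival offset. Heuristic bolus descriptors (appearance
# time, peak time, peak intensity, wash-in time) complement the model fit.

#' Construct a time-intensity curve
#'
#' @param t Seconds, strictly increasing.
#' @param y Linear intensity (a.u.), same length.
#' @param pixel Optional `(row, col)` provenance.
#' @return An object of class `tic`.
#' @export
tic <- function(t, y, pixel = c(NA_integer_, NA_integer_)) {
  if (length(t) != length(y)) stop("t and y must have equal length")
  if (any(diff(t) <= 0)) stop("t must be strictly increasing")
  structure(list(t = as.numeric(t), y = as.numeric(y), pixel = pixel,
                 valid = TRUE),
            class = "tic")
}

#' Evaluate the LDRW bolus model
#'
#' @param t Seconds.
#' @param alpha Area under the curve (a.u.*s), > 0.
#' @param kappa Dispersion-related rate (1/s), > 0.
#' @param mu Mean transit time (s), > 0.
#' @param t0 Arrival offset (s); the curve is 0 for `t <= t0`.
#' @return Model intensities, same length as `t`.
#' @export
ldrw_curve <- function(t, alpha, kappa, mu, t0 = 0) {
  tau <- t - t0
  out <- numeric(length(t))
  pos <- tau > 0
  tp <- tau[pos]
  out[pos] <- alpha * sqrt(kappa / (2 * pi * tp)) *
    exp(-kappa * (tp - mu)^2 / (2 * tp))
  out
}

# Zero-phase low-pass (squared Butterworth magnitude applied in the
# frequency domain) on a (time x pixel) matrix; length preserved.
lowpass_matrix <- function(Y, t, cutoff_hz, order = 4) {
  n <- nrow(Y)
  dt <- mean(diff(t))
  f <- c(seq(0, floor(n / 2)), seq(-(ceiling(n / 2) - 1), -1)) / (n * dt)
  H <- 1 / (1 + (abs(f) / cutoff_hz)^(2 * order))
  Re(stats::mvfft(stats::mvfft(Y) * H, inverse = TRUE)) / n
}

trapz <- function(t, y) sum(diff(t) * (head(y, -1) + y[-1]) / 2)

# Matrix preprocessing core: baseline (median of the first
# baseline_window_s seconds) subtraction, zero-phase low-pass, then
# clipping at zero. Clipping after (not before) filtering avoids
# rectifying pre-arrival noise into a positive bias. Y is (time x pixel).
preprocess_matrix <- function(Y, t, config) {
  base_idx <- which(t <= t[1] + config$baseline_window_s)
  base <- apply(Y[base_idx, , drop = FALSE], 2, median)
  Y <- sweep(Y, 2, base)
  Y <- lowpass_matrix(Y, t, config$lowpass_hz)
  Y[Y < 0] <- 0
  Y
}

#' Preprocess a TIC for model fitting
#'
#' Subtracts the pre-arrival baseline (median of the first
#' `baseline_window_s` seconds of the record), applies a zero-phase
#' low-pass at `lowpass_hz`, and clips at zero. Curves with fewer than 20
#' samples or spanning less than 60 s cannot support a bolus fit and are
#' flagged invalid.
#'
#' @param x A [tic()].
#' @param config Optional [run_config()].
#' @return A [tic()] with filtered `y`; `$valid` is `FALSE` if the record
#'   is too short.
#' @export
preprocess_tic <- function(x, config = NULL) {
  config <- as_run_config(config)
  stopifnot(inherits(x, "tic"))
  if (length(x$t) < 20 || diff(range(x$t)) < 60) {
    x$valid <- FALSE
    return(x)
  }
  x$y <- drop(preprocess_matrix(matrix(x$y, ncol = 1), x$t, config))
  x
}

#' Heuristic bolus parameters of a preprocessed TIC
#'
#' Peak intensity `PI` is the maximum of the (smoothed) curve; peak time
#' `PT` the time of its first maximum; appearance time `AT` the first
#' crossing of 5\% of `PI`; wash-in time `WIT` the 10\%-to-90\% rise time
#' on the rising limb. A curve with zero peak has no bolus and all fields
#' are invalid.
#'
#' @param x A preprocessed [tic()].
#' @param config Optional [run_config()].
#' @return List with `AT`, `PT`, `PI`, `WIT` (seconds / a.u.), all `NA`
#'   when invalid, plus `valid`.
#' @export
heuristic_params <- function(x, config = NULL) {
  config <- as_run_config(config)
  t <- x$t; y <- x$y
  invalid <- list(AT = NA_real_, PT = NA_real_, PI = NA_real_,
                  WIT = NA_real_, valid = FALSE)
  if (!isTRUE(x$valid)) return(invalid)
  pi_v <- max(y)
  if (!is.finite(pi_v) || pi_v <= 0) return(invalid)
  pk <- which.max(y)
  at_i <- which(y >= config$at_threshold * pi_v)[1]
  rise <- seq_len(pk)
  lo_i <- which(y[rise] >= config$wit_fractions[1] * pi_v)[1]
  hi_i <- which(y[rise] >= config$wit_fractions[2] * pi_v)[1]
  wit <- if (is.na(lo_i) || is.na(hi_i)) NA_real_ else t[hi_i] - t[lo_i]
  list(AT = t[at_i], PT = t[pk], PI = pi_v, WIT = wit, valid = TRUE)
}

#' Fit the LDRW bolus model to a preprocessed TIC
#'
#' Nonlinear least squares (Levenberg-Marquardt, bounded) over
#' `(alpha, kappa, mu, t0)`. Starting values come from curve moments:
#' `t0` one second before the appearance time, `mu` the intensity-weighted
#' mean of `t - t0`, `alpha` the trapezoidal integral, and
#' `kappa = mu / var` from the intensity-weighted variance. `t0` is
#' bounded within `[t_min, AT]`. Non-convergence, a parameter pinned at a
#' bound, or a curve without energy marks the fit invalid.
#'
#' @param x A preprocessed [tic()].
#' @param config Optional [run_config()].
#' @param maxiter LM iteration cap.
#' @return An `ldrw_fit`: list with `alpha`, `kappa`, `mu`, `t0`,
#'   `baseline` (0 for preprocessed input), `rss`, `converged`.
#' @export
fit_ldrw <- function(x, config = NULL, maxiter = 500) {
  config <- as_run_config(config)
  t <- x$t; y <- x$y
  bad <- structure(list(alpha = NA_real_, kappa = NA_real_, mu = NA_real_,
                        t0 = NA_real_, baseline = 0, rss = NA_real_,
                        converged = FALSE), class = "ldrw_fit")
  if (!isTRUE(x$valid) || !any(y > 0)) return(bad)
  h <- heuristic_params(x, config)
  if (!h$valid) return(bad)
  t0_init <- max(h$AT - 1, t[1])
  w <- pmax(y, 0)
  mu_init <- sum(w * (t - t0_init)) / sum(w)
  v_init <- sum(w * (t - t0_init - mu_init)^2) / sum(w)
  kappa_init <- if (v_init > 0) max(mu_init / v_init, 1e-3) else 1
  alpha_init <- max(trapz(t, w), 1e-6)
  mu_init <- max(mu_init, 1e-2)
  lower <- c(alpha = 1e-9, kappa = 1e-6, mu = 1e-3, t0 = t[1])
  upper <- c(alpha = Inf, kappa = Inf, mu = Inf, t0 = max(h$AT, t[1] + 1e-6))
  start <- c(alpha = alpha_init, kappa = kappa_init, mu = mu_init,
             t0 = min(max(t0_init, lower["t0"]), upper["t0"]))
  res <- try(minpack.lm::nls.lm(
    par = start,
    lower = lower, upper = upper,
    fn = function(p) y - ldrw_curve(t, p[1], p[2], p[3], p[4]),
    control = minpack.lm::nls.lm.control(maxiter = maxiter, ftol = 1e-8,
                                         ptol = 1e-10)), silent = TRUE)
  if (inherits(res, "try-error")) return(bad)
  p <- res$par
  at_bound <- p[1] <= lower[1] * (1 + 1e-6) || p[2] <= lower[2] * (1 + 1e-6) ||
    p[3] <= lower[3] * (1 + 1e-6)
  ok <- res$info %in% 1:4 && !at_bound && all(is.finite(p))
  structure(list(alpha = unname(p[1]), kappa = unname(p[2]),
                 mu = unname(p[3]), t0 = unname(p[4]), baseline = 0,
                 rss = sum(res$fvec^2), converged = ok),
            class = "ldrw_fit")
}

# Vectorized heuristics on a preprocessed (time x pixel) matrix.
heuristics_matrix <- function(Y, t, config) {
  npx <- ncol(Y)
  if (npx == 0)
    return(list(AT = numeric(0), PT = numeric(0), PI = numeric(0),
                WIT = numeric(0), valid = logical(0)))
  PI <- apply(Y, 2, max)
  valid <- PI > 0
  Yt <- t(Y)
  pk <- max.col(Yt, ties.method = "first")
  first_cross <- function(frac, limit = NULL) {
    thr <- frac * PI
    M <- Yt >= thr
    if (!is.null(limit)) {
      cols <- col(M)
      M <- M & cols <= limit
    }
    any_hit <- rowSums(M) > 0
    idx <- max.col(M, ties.method = "first")
    ifelse(any_hit, idx, NA_integer_)
  }
  at_i <- first_cross(config$at_threshold)
  lo_i <- first_cross(config$wit_fractions[1], pk)
  hi_i <- first_cross(config$wit_fractions[2], pk)
  list(AT = ifelse(valid & !is.na(at_i), t[at_i], NA_real_),
       PT = ifelse(valid, t[pk], NA_real_),
       PI = ifelse(valid, PI, NA_real_),
       WIT = ifelse(valid & !is.na(lo_i) & !is.na(hi_i),
                    t[hi_i] - t[lo_i], NA_real_),
       valid = valid)
}

# Extract the (time x pixel) TIC matrix for the masked pixels of a loop.
tic_matrix <- function(dce, mask) {
  d <- dim(dce$frames)
  M <- matrix(dce$frames, d[1], d[2] * d[3])
  M[, which(mask), drop = FALSE]
}

#' Per-pixel bolus-model parametric maps
#'
#' Fits the LDRW model and extracts heuristic bolus parameters for every
#' pixel of the prostate mask of a (motion-compensated) loop, producing
#' the `mu`, `kappa`, `alpha`, `AT`, `PT`, `PI` and `WIT` maps. Pixels
#' whose fit fails to converge are flagged invalid, never zeroed.
#'
#' @param dce A [dce_plane()].
#' @param prostate_mask Logical matrix on the frame grid.
#' @param config Optional [run_config()].
#' @return Named list of [param_map()]s.
#' @export
tic_maps <- function(dce, prostate_mask, config = NULL) {
  config <- as_run_config(config)
  shp <- frame_shape(dce)
  idx <- which(prostate_mask)
  units <- param_units()
  empty <- function(nm) param_map(nm, matrix(NA_real_, shp[1], shp[2]),
                                  units = units[[nm]])
  out <- lapply(setNames(nm = c("mu", "kappa", "alpha", "AT", "PT", "PI",
                                "WIT")), empty)
  if (!length(idx)) return(out)
  t <- dce$timestamps
  Y <- preprocess_matrix(tic_matrix(dce, prostate_mask), t, config)
  too_short <- length(t) < 20 || diff(range(t)) < 60
  h <- heuristics_matrix(Y, t, config)
  fill <- function(nm, vals, ok) {
    m <- matrix(NA_real_, shp[1], shp[2])
    m[idx[ok]] <- vals[ok]
    param_map(nm, m, units = units[[nm]])
  }
  hv <- h$valid & !too_short
  out$AT <- fill("AT", h$AT, hv & !is.na(h$AT))
  out$PT <- fill("PT", h$PT, hv)
  out$PI <- fill("PI", h$PI, hv)
  out$WIT <- fill("WIT", h$WIT, hv & !is.na(h$WIT))
  if (too_short) return(out)
  np <- length(idx)
  mu_v <- kappa_v <- alpha_v <- rep(NA_real_, np)
  okf <- rep(FALSE, np)
  for (j in seq_len(np)) {
    if (!h$valid[j]) next
    tj <- structure(list(t = t, y = Y[, j], pixel = NULL, valid = TRUE),
                    class = "tic")
    f <- fit_ldrw(tj, config)
    if (f$converged) {
      mu_v[j] <- f$mu; kappa_v[j] <- f$kappa; alpha_v[j] <- f$alpha
      okf[j] <- TRUE
    }
  }
  out$mu <- fill("mu", mu_v, okf)
  out$kappa <- fill("kappa", kappa_v, okf)
  out$alpha <- fill("alpha", alpha_v, okf)
  out
}
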