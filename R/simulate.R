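# Ground-truth-bearing simulator of multiparametric planes.
#
# Each synthetic plane carries a prostate ellipse with an anterior
# transition-zone (TZ) ellipse, zero to two lesions, per-pixel contrast
# kinetics drawn from the LDRW closed form with tissue-dependent
# parameters and a flow-axis arrival-delay field (so neighboring pixels
# are coupled through convective transport), a stiffness map in which
# healthy TZ tissue is stiffer than PZ tissue and lesions are stiffer
# than their host zone, a speckled B-mode image with bright
# calcification disks, and balanced benign/malignant regions of
# interest. All ground truths are recorded.

#' Simulator configuration
#'
#' Defaults define the reference study conditions: three planes per
#' patient on a 144 x 192 px grid at 0.167 mm/px, a 2-minute loop at
#' 5 Hz, malignant tissue with shorter mean transit time, larger bolus
#' area, higher contrast velocity and higher stiffness than its host
#' zone, TZ stiffer than PZ, and patient-level heterogeneity that keeps
#' single parameters imperfect discriminators.
#'
#' @param n_patients Number of patients.
#' @param planes_per_patient Imaging planes per patient (apex/mid/base).
#' @param grid `(rows, cols)` in px.
#' @param pixel_spacing mm/px.
#' @param frame_rate Hz.
#' @param duration Seconds of DCE-US recording.
#' @param kinetics Per-tissue LDRW parameters and flow constants; see
#'   defaults.
#' @param stiffness Per-tissue Young's modulus means/SDs (kPa).
#' @param echogenicity B-mode mean gray level per tissue.
#' @param lesion_radius_mm Range of lesion radii.
#' @param second_lesion_prob Probability of an additional unlabeled
#'   lesion.
#' @param roi_radius_mm Radius of the benign and malignant ROI disks.
#' @param calc_rate Expected calcifications per plane (Poisson).
#' @param calc_radius_mm Range of calcification radii.
#' @param tic_noise Additive TIC noise as a fraction of the per-pixel
#'   peak (0 disables).
#' @param patient_sd Log-scale SD of patient-level multipliers
#'   (kinetics, stiffness, flow drawn independently).
#' @param field_rel_sd Relative SD of the smooth within-plane parameter
#'   fields.
#' @param motion_amplitude_mm Peak rigid drift applied to the loop (0
#'   disables).
#' @param motion_rot_deg Peak rigid rotation (degrees).
#' @param effect_scale Scales every malignant offset; 0 gives the null
#'   simulator in which lesions are kinetically and elastically
#'   indistinguishable from their host zone.
#' @param family `"ldrw"` (well-specified) or `"gamma"` (gamma-variate
#'   mis-specification mode for robustness checks).
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(n_patients = 12,
                       planes_per_patient = 3,
                       grid = c(144, 192),
                       pixel_spacing = 0.167,
                       frame_rate = 5,
                       duration = 120,
                       kinetics = list(
                         pz = list(mu = 25, kappa = 0.5, alpha = 60,
                                   v = 0.5, D = 0.15),
                         tz = list(mu = 28, kappa = 0.4, alpha = 80,
                                   v = 0.6, D = 0.15),
                         lesion = list(mu_factor = 0.82, kappa_factor = 1.25,
                                       alpha_factor = 1.22, v_offset = 0.3,
                                       D_offset = 0.05)),
                       stiffness = list(pz = 22, tz = 35, lesion_delta = 10,
                                        field_sd = c(pz = 4, tz = 5,
                                                     lesion = 6)),
                       echogenicity = list(pz = 0.55, tz = 0.45,
                                           lesion_factor = 0.92),
                       lesion_radius_mm = c(1.8, 3.0),
                       second_lesion_prob = 0.3,
                       roi_radius_mm = 1.3,
                       calc_rate = 0.7,
                       calc_radius_mm = c(0.5, 1.5),
                       tic_noise = 0.08,
                       patient_sd = 0.30,
                       field_rel_sd = 0.15,
                       motion_amplitude_mm = 0,
                       motion_rot_deg = 0,
                       effect_scale = 1,
                       family = c("ldrw", "gamma")) {
  cfg <- as.list(environment())
  cfg$family <- match.arg(family)
  if (cfg$n_patients < 1 || cfg$planes_per_patient < 1)
    stop("cohort must contain patients and planes")
  if (any(cfg$grid < 24)) stop("grid too small to host a prostate")
  class(cfg) <- "sim_config"
  cfg
}

disk_offsets <- function(radius_mm, spacing) {
  r_px <- max(1, round(radius_mm / spacing))
  g <- expand.grid(dr = -r_px:r_px, dc = -r_px:r_px)
  g[g$dr^2 + g$dc^2 <= r_px^2, ]
}

in_ellipse <- function(nr, nc, center, semi) {
  r <- matrix(seq_len(nr), nr, nc)
  c2 <- matrix(seq_len(nc), nr, nc, byrow = TRUE)
  ((r - center[1]) / semi[1])^2 + ((c2 - center[2]) / semi[2])^2 <= 1
}

smooth_field <- function(nr, nc, sigma_px) {
  f <- gaussian_smooth(matrix(rnorm(nr * nc), nr, nc), sigma_px)
  f / sd(f)
}

# Place a disk of given pixel offsets fully inside `allowed`; returns the
# integer center or NULL.
place_disk <- function(allowed, offs, tries = 200) {
  nr <- nrow(allowed); nc <- ncol(allowed)
  cand <- which(allowed)
  if (!length(cand)) return(NULL)
  for (i in seq_len(tries)) {
    p <- cand[sample.int(length(cand), 1)]
    r0 <- ((p - 1) %% nr) + 1; c0 <- ((p - 1) %/% nr) + 1
    rr <- r0 + offs$dr; cc <- c0 + offs$dc
    if (any(rr < 1 | rr > nr | cc < 1 | cc > nc)) next
    if (all(allowed[cbind(rr, cc)])) return(c(r0, c0))
  }
  NULL
}

disk_mask <- function(nr, nc, center, offs) {
  m <- matrix(FALSE, nr, nc)
  rr <- center[1] + offs$dr; cc <- center[2] + offs$dc
  ok <- rr >= 1 & rr <= nr & cc >= 1 & cc <= nc
  m[cbind(rr[ok], cc[ok])] <- TRUE
  m
}

bolus_curve <- function(t, alpha, kappa, mu, t0, family) {
  if (family == "ldrw") return(ldrw_curve(t, alpha, kappa, mu, t0))
  tau <- t - t0
  out <- numeric(length(t))
  pos <- tau > 0
  out[pos] <- alpha * stats::dgamma(tau[pos], shape = mu * kappa,
                                    rate = kappa)
  out
}

simulate_plane <- function(cfg, plane_id, patient, jit, lesion_zone) {
  nr <- cfg$grid[1]; nc <- cfg$grid[2]
  sp <- cfg$pixel_spacing
  s <- cfg$effect_scale
  center <- c(nr / 2, nc / 2)
  semi <- c(0.40 * nr, 0.42 * nc) * runif(1, 0.92, 1.0)
  prostate <- in_ellipse(nr, nc, center, semi)
  tz <- in_ellipse(nr, nc, center - c(0.18 * semi[1], 0),
                   0.55 * semi) & prostate
  zone <- matrix(ZONE_OUTSIDE, nr, nc)
  zone[prostate] <- ZONE_PZ
  zone[tz] <- ZONE_TZ

  # lesions: the first hosts the malignant ROI in the requested zone
  grade <- sample(1:3, 1, prob = c(0.3, 0.4, 0.3))
  ge <- c(0.5, 1, 1.5)[grade] * s   # grade-scaled, zero in null mode
  roi_offs <- disk_offsets(cfg$roi_radius_mm, sp)
  lesion_r <- max(runif(1, cfg$lesion_radius_mm[1], cfg$lesion_radius_mm[2]),
                  cfg$roi_radius_mm + 0.3)
  lesion_offs <- disk_offsets(lesion_r, sp)
  zone_ok <- if (lesion_zone == ZONE_PZ) zone == ZONE_PZ else zone == ZONE_TZ
  # erode allowed region so the ROI disk stays well inside the lesion
  ctr <- place_disk(zone_ok, lesion_offs)
  if (is.null(ctr)) ctr <- place_disk(zone_ok, roi_offs)
  if (is.null(ctr)) stop("could not place a lesion inside the requested zone")
  lesion <- disk_mask(nr, nc, ctr, lesion_offs) & prostate
  # benign ROI in the other zone, away from the lesion; both ROIs share
  # one offset set (identical pixel counts), shrunk together if the zone
  # geometry is tight. The benign center must admit the same lesion-sized
  # disk as the malignant one, so both classes sample interior positions
  # of their zones identically (a positional asymmetry would leak label
  # information through border-dependent radiomics even in the null).
  other_ok <- (if (lesion_zone == ZONE_PZ) zone == ZONE_TZ else
    zone == ZONE_PZ) & !lesion
  ctr_b <- place_disk(other_ok, lesion_offs)
  roi_offs <- disk_offsets(cfg$roi_radius_mm, sp)
  if (is.null(ctr_b)) {
    for (roi_r in unique(c(cfg$roi_radius_mm, 1.0, 0.8, 0.5))) {
      roi_offs <- disk_offsets(roi_r, sp)
      ctr_b <- place_disk(other_ok, roi_offs)
      if (!is.null(ctr_b)) break
    }
  }
  if (is.null(ctr_b)) stop("could not place the benign ROI")
  roi_mal <- disk_mask(nr, nc, ctr, roi_offs)
  roi_ben <- disk_mask(nr, nc, ctr_b, roi_offs)
  # optional second, unlabeled lesion anywhere in the prostate outside
  # both labeled regions
  if (runif(1) < cfg$second_lesion_prob) {
    off2 <- disk_offsets(runif(1, cfg$lesion_radius_mm[1],
                                cfg$lesion_radius_mm[2]), sp)
    ctr2 <- place_disk(prostate & !lesion & !roi_ben, off2, tries = 50)
    if (!is.null(ctr2)) {
      l2 <- disk_mask(nr, nc, ctr2, off2) & prostate
      if (!any(l2 & (roi_mal | roi_ben))) lesion <- lesion | l2
    }
  }
  roi <- matrix(ROI_UNLABELED, nr, nc)
  roi[roi_ben] <- ROI_BENIGN
  roi[roi_mal] <- ROI_MALIGNANT

  ## ---- per-pixel kinetic truths ----------------------------------------
  kin <- cfg$kinetics
  les <- kin$lesion
  f_mu <- smooth_field(nr, nc, 1.5 / sp)
  f_al <- smooth_field(nr, nc, 1.5 / sp)
  f_ka <- smooth_field(nr, nc, 1.5 / sp)
  pick <- function(pz_val, tz_val) ifelse(zone == ZONE_TZ, tz_val, pz_val)
  mu_t <- pick(kin$pz$mu, kin$tz$mu)
  ka_t <- pick(kin$pz$kappa, kin$tz$kappa)
  al_t <- pick(kin$pz$alpha, kin$tz$alpha)
  v_t <- pick(kin$pz$v, kin$tz$v)
  D_t <- pick(kin$pz$D, kin$tz$D)
  mu_t[lesion] <- mu_t[lesion] * (1 + (les$mu_factor - 1) * ge)
  ka_t[lesion] <- ka_t[lesion] * (1 + (les$kappa_factor - 1) * ge)
  al_t[lesion] <- al_t[lesion] * (1 + (les$alpha_factor - 1) * ge)
  v_t[lesion] <- v_t[lesion] + les$v_offset * ge
  D_t[lesion] <- D_t[lesion] + les$D_offset * ge
  mu_px <- mu_t * jit$kin * (1 + cfg$field_rel_sd * f_mu)
  ka_px <- ka_t * jit$kin * (1 + cfg$field_rel_sd * f_ka)
  al_px <- al_t * jit$flow * (1 + 1.5 * cfg$field_rel_sd * f_al)
  mu_px <- pmax(mu_px, 2); ka_px <- pmax(ka_px, 0.05)
  al_px <- pmax(al_px, 1)

  # flow-axis arrival delays couple neighbors through local velocity
  phi <- runif(1, 0, 2 * pi)
  r_i <- matrix(seq_len(nr), nr, nc)
  c_i <- matrix(seq_len(nc), nr, nc, byrow = TRUE)
  proj <- (r_i * sin(phi) + c_i * cos(phi)) * sp
  proj <- proj - min(proj[prostate])
  t0_pat <- jit$t0
  t0_px <- t0_pat + proj / (v_t * jit$flow)

  ## ---- DCE loop ---------------------------------------------------------
  nt <- round(cfg$duration * cfg$frame_rate) + 1
  t <- seq(0, cfg$duration, length.out = nt)
  idx <- which(prostate)
  np <- length(idx)
  # static echo texture acts as a per-pixel gain on the bolus amplitude
  tex <- 1 + 0.25 * (matrix(stats::rgamma(nr * nc, 4, 4), nr, nc) - 1)
  al_px <- al_px * tex
  Y <- matrix(0, nt, np)
  for (j in seq_len(np)) {
    p <- idx[j]
    Y[, j] <- bolus_curve(t, al_px[p], ka_px[p], mu_px[p], t0_px[p],
                          cfg$family)
  }
  frames <- array(0.5, c(nt, nr, nc))
  Fmat <- matrix(frames, nt, nr * nc)
  Fmat[, idx] <- Fmat[, idx] + Y
  if (cfg$tic_noise > 0) {
    peak <- pmax(apply(Fmat, 2, max), 1)
    Fmat <- Fmat + matrix(rnorm(length(Fmat)), nt) *
      rep(cfg$tic_noise * peak, each = nt)
    Fmat[Fmat < 0] <- 0
  }
  frames <- array(Fmat, c(nt, nr, nc))
  if (cfg$motion_amplitude_mm > 0) {
    drift <- cfg$motion_amplitude_mm / sp
    for (i in seq_len(nt)) {
      u <- (i - 1) / (nt - 1)
      frames[i, , ] <- rigid_warp(frames[i, , ],
                                  tx_px = drift * u,
                                  ty_px = 0.6 * drift * sin(2 * pi * u),
                                  rot_deg = cfg$motion_rot_deg * u)
    }
  }
  dce <- dce_plane(frames, t, sp, patient, plane_id)

  ## ---- SWE and B-mode ----------------------------------------------------
  st <- cfg$stiffness
  E_base <- pick(st$pz, st$tz)
  E_base[lesion] <- E_base[lesion] + st$lesion_delta * ge
  f_E <- smooth_field(nr, nc, 2 / sp)
  sd_E <- pick(st$field_sd["pz"], st$field_sd["tz"])
  sd_E[lesion] <- st$field_sd["lesion"]
  E <- pmax(E_base * jit$stiff + sd_E * f_E, 2)
  E[!prostate] <- pmax(15 + 3 * f_E[!prostate], 2)

  echo <- pick(cfg$echogenicity$pz, cfg$echogenicity$tz)
  echo[lesion] <- echo[lesion] * cfg$echogenicity$lesion_factor
  echo[!prostate] <- 0.35
  G <- echo * matrix(stats::rgamma(nr * nc, 4, 4), nr, nc)

  calc <- matrix(FALSE, nr, nc)
  n_calc <- rpois(1, cfg$calc_rate)
  for (i in seq_len(n_calc)) {
    co <- disk_offsets(runif(1, cfg$calc_radius_mm[1], cfg$calc_radius_mm[2]),
                       sp)
    cc <- place_disk(prostate, co, tries = 50)
    if (is.null(cc)) next
    cm <- disk_mask(nr, nc, cc, co)
    calc <- calc | cm
    G[cm] <- G[cm] + 4 * mean(echo[prostate])
    E[cm] <- E[cm] + 40
  }

  bundle <- plane_bundle(dce, bmode = G, swe = E,
                         prostate_mask = prostate, zone_mask = zone,
                         calcification_mask = calc, roi_labels = roi)
  truth <- list(tissue = zone + 2L * (lesion & prostate),
                lesion_mask = lesion, roi_labels = roi,
                mu = mu_px, kappa = ka_px, alpha = al_px,
                v = v_t * jit$flow, D = D_t, E = E, t0 = t0_px,
                grade = grade, lesion_zone = lesion_zone)
  truth$mu[!prostate] <- NA; truth$kappa[!prostate] <- NA
  truth$alpha[!prostate] <- NA; truth$v[!prostate] <- NA
  truth$D[!prostate] <- NA
  list(bundle = bundle, truth = truth)
}

#' Simulate one patient
#'
#' Generates `planes_per_patient` co-registered plane bundles with ground
#' truth. Patient-level heterogeneity (independent log-normal multipliers
#' for kinetics, stiffness and flow, and an arrival-time offset) makes
#' patients exchangeable but not identical, as in a clinical cohort.
#'
#' @param cfg A [sim_config()].
#' @param patient_seed Integer seed; the same seed reproduces the patient
#'   bit-identically.
#' @param patient_id Identifier string.
#' @param zone_parity 0 or 1; alternates which zone hosts the malignant
#'   ROI across planes, keeping PZ/TZ provenance balanced.
#' @return List with `bundles` (list of [plane_bundle()]) and `truth`
#'   (per-plane ground-truth list).
#' @export
simulate_patient <- function(cfg, patient_seed, patient_id = "P01",
                             zone_parity = 0) {
  set.seed(patient_seed)
  jit <- list(kin = exp(rnorm(1, 0, cfg$patient_sd)),
              stiff = exp(rnorm(1, 0, cfg$patient_sd)),
              flow = exp(rnorm(1, 0, cfg$patient_sd)),
              t0 = min(max(rnorm(1, 12, 1.5), 9), 16))
  plane_ids <- c("apex", "mid", "base", paste0("x", seq_len(max(0,
    cfg$planes_per_patient - 3))))[seq_len(cfg$planes_per_patient)]
  bundles <- list(); truth <- list()
  for (k in seq_along(plane_ids)) {
    zone <- if ((zone_parity + k) %% 2 == 0) ZONE_PZ else ZONE_TZ
    pl <- simulate_plane(cfg, plane_ids[k], patient_id, jit, zone)
    bundles[[plane_ids[k]]] <- pl$bundle
    truth[[plane_ids[k]]] <- pl$truth
  }
  list(bundles = bundles, truth = truth, patient_id = patient_id)
}

#' Simulate a cohort
#'
#' Generates `n_patients` patients with per-patient seeds derived from
#' `seed`, verifies the ROI balance invariant (benign vs malignant ROI
#' pixel totals, and PZ- vs TZ-originating ROI pixels, within 10\% of
#' each other), and optionally writes the dataset to disk in the plane
#' bundle layout with a manifest.
#'
#' @param cfg A [sim_config()].
#' @param seed Integer master seed.
#' @param dir Optional output directory.
#' @return An `mpus_cohort`: list with `patients`, `config`, `seed`.
#' @export
simulate_cohort <- function(cfg = sim_config(), seed = 1, dir = NULL) {
  if (cfg$n_patients < 8)
    stop("a cohort needs at least 8 patients for leave-one-patient-out use")
  patients <- vector("list", cfg$n_patients)
  ids <- sprintf("P%02d", seq_len(cfg$n_patients))
  for (i in seq_len(cfg$n_patients)) {
    patients[[i]] <- simulate_patient(cfg, fold_seed(seed, i), ids[i],
                                      zone_parity = i %% 2)
  }
  names(patients) <- ids
  cohort <- structure(list(patients = patients, config = cfg, seed = seed),
                      class = "mpus_cohort")
  bal <- roi_balance(cohort)
  if (abs(bal$benign - bal$malignant) > 0.1 * max(bal$benign, bal$malignant))
    stop("ROI class balance violated")
  if (abs(bal$pz - bal$tz) > 0.1 * max(bal$pz, bal$tz))
    stop("ROI zonal balance violated")
  if (!is.null(dir)) {
    for (id in ids) {
      for (pl in names(patients[[id]]$bundles)) {
        write_plane_bundle(patients[[id]]$bundles[[pl]],
                           file.path(dir, id, pl))
      }
    }
    manifest <- list(patients = ids,
                     planes = names(patients[[1]]$bundles),
                     seed = seed,
                     n_patients = cfg$n_patients,
                     grid = cfg$grid, pixel_spacing = cfg$pixel_spacing)
    yaml::write_yaml(manifest, file.path(dir, "manifest.yaml"))
  }
  cohort
}

#' ROI pixel balance of a cohort
#'
#' @param cohort An `mpus_cohort`.
#' @return List with total benign, malignant, PZ- and TZ-originating ROI
#'   pixel counts.
#' @export
roi_balance <- function(cohort) {
  ben <- mal <- pz <- tz <- 0
  for (p in cohort$patients) {
    for (b in p$bundles) {
      ben <- ben + sum(b$roi_labels == ROI_BENIGN)
      mal <- mal + sum(b$roi_labels == ROI_MALIGNANT)
      lab <- b$roi_labels != ROI_UNLABELED
      pz <- pz + sum(lab & b$zone_mask == ZONE_PZ)
      tz <- tz + sum(lab & b$zone_mask == ZONE_TZ)
    }
  }
  list(benign = ben, malignant = mal, pz = pz, tz = tz)
}

#' Load a simulated cohort from disk
#'
#' @param dir Directory written by [simulate_cohort()].
#' @param config Optional [run_config()] passed to the bundle loader.
#' @return An `mpus_cohort` without ground truth (as for clinical data).
#' @export
load_cohort <- function(dir, config = NULL) {
  manifest <- yaml::read_yaml(file.path(dir, "manifest.yaml"))
  patients <- list()
  for (id in manifest$patients) {
    bundles <- list()
    for (pl in manifest$planes)
      bundles[[pl]] <- load_plane_bundle(file.path(dir, id, pl), config)
    patients[[id]] <- list(bundles = bundles, truth = NULL,
                           patient_id = id)
  }
  structure(list(patients = patients, config = NULL,
                 seed = manifest$seed), class = "mpus_cohort")
}
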