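#' Gamma-variate arterial input function
#'
#' The standard bolus shape `A (t - t0)^shape exp(-(t - t0)/scale)` for
#' `t > t0`, zero before the delay. The amplitude `A` is chosen so the
#' curve peaks (at `t0 + shape * scale`) at `peak` mmol/L; the default
#' peak of 1 mmol/L matches the typical post-bolus blood concentration
#' after a standard intravenous dose.
#'
#' @param t Time in seconds from injection; vectorized.
#' @param peak Peak blood concentration in mmol/L.
#' @param delay Bolus arrival delay `t0` in seconds.
#' @param shape,scale Gamma-variate shape (dimensionless) and scale (s);
#'   both must be positive.
#' @return Concentration in mmol/L at each `t`.
#' @export
#' @examples
#' gamma_variate_aif(seq(0, 60, 5))
gamma_variate_aif <- function(t, peak = 1, delay = 20, shape = 1, scale = 2.4) {
  if (shape <= 0 || scale <= 0) {
    stop("shape and scale must be positive", call. = FALSE)
  }
  if (peak < 0) stop("peak must be non-negative", call. = FALSE)
  A <- peak / ((shape * scale)^shape * exp(-shape))
  u <- t - delay
  ifelse(u > 0, A * u^shape * exp(-u / scale), 0)
}

# Running integral of the gamma-variate AIF (mmol s / L), closed form via
# the regularized incomplete gamma function.
.aif_integral <- function(t, peak, delay, shape, scale) {
  A <- peak / ((shape * scale)^shape * exp(-shape))
  total <- A * scale^(shape + 1) * gamma(shape + 1)
  u <- pmax(t - delay, 0)
  total * stats::pgamma(u, shape = shape + 1, scale = scale)
}

#' Kinetic parameters of the synthetic contrast phantom
#'
#' Minimal one-compartment kinetics reproducing the qualitative dynamics
#' the analysis expects: a bolus-driven rapid uptake into CSF near the
#' choroid plexus (onset at the AIF delay, plateau once the bolus has
#' passed), and a slow delayed ventricle-wide accumulation reaching its
#' plateau at the 4 h time point. This is a test fixture, not a
#' physiological claim.
#'
#' The CP uptake is `dC/dt = k_in * C_aif(t) - k_out * C`; with the default
#' `k_out = 0` the transfer constant `k_in` is derived from
#' `plateau_c_cp / integral(aif)` so the CP curve plateaus exactly at
#' `plateau_c_cp`. Slow compartments follow a delayed saturating
#' exponential normalized to hit their plateau at `t_4h`.
#'
#' @param aif List of gamma-variate parameters (`peak`, `delay`, `shape`,
#'   `scale`), see [gamma_variate_aif()].
#' @param bcsfb_transfer Transfer rate `k_in` in 1/s, or `NULL` (default)
#'   to derive it from `plateau_c_cp`.
#' @param k_out Clearance rate in 1/s (default 0).
#' @param plateau_c_cp Programmed CP plateau concentration, mmol/L.
#' @param plateau_c_lv_4h Programmed rest-of-LV concentration at 4 h,
#'   mmol/L.
#' @param dispersion_to_lv List with `delay` (s) and `tau` (s): delay and
#'   time constant of the slow ventricle-wide accumulation.
#' @param cgm_scale Perivascular cGM 4 h plateau as a fraction of the LV
#'   plateau.
#' @param t_4h Time of the delayed session, seconds post-injection.
#' @param dip Optional bolus-phase transient on CP/transition/cGM signals:
#'   list with `depth` (percent), `center` (s), `width` (s); `NULL` for
#'   none.
#' @return A `kinetic_params` object.
#' @export
kinetic_params <- function(aif = list(peak = 1, delay = 20, shape = 1,
                                      scale = 2.4),
                           bcsfb_transfer = NULL, k_out = 0,
                           plateau_c_cp = 0.027, plateau_c_lv_4h = 0.050,
                           dispersion_to_lv = list(delay = 300, tau = 5000),
                           cgm_scale = 0.97, t_4h = 14400, dip = NULL) {
  stopifnot(plateau_c_cp >= 0, plateau_c_lv_4h >= 0, k_out >= 0,
            dispersion_to_lv$delay >= 0, dispersion_to_lv$tau > 0)
  total_aif <- .aif_integral(Inf, aif$peak, aif$delay, aif$shape, aif$scale)
  if (is.null(bcsfb_transfer)) {
    bcsfb_transfer <- if (total_aif > 0) plateau_c_cp / total_aif else 0
  }
  stopifnot(bcsfb_transfer >= 0)
  structure(
    list(aif = aif, bcsfb_transfer = bcsfb_transfer, k_out = k_out,
         plateau_c_cp = plateau_c_cp, plateau_c_lv_4h = plateau_c_lv_4h,
         dispersion_to_lv = dispersion_to_lv, cgm_scale = cgm_scale,
         t_4h = t_4h, dip = dip),
    class = "kinetic_params"
  )
}

#' Programmed CSF concentration curve of the phantom
#'
#' Concentration as a function of time post-injection for one region.
#' The CP follows one-compartment uptake from the AIF (closed form when
#' `k_out = 0`, explicit Euler on the supplied grid otherwise); the rest
#' of the lateral ventricle and perivascular cGM follow the slow delayed
#' accumulation, essentially zero during the first minutes and reaching
#' their programmed plateaus at the 4 h sample; the transition shell is an
#' equal mixture of the CP and LV curves.
#'
#' @param t Time in seconds post-injection (the acquisition grid);
#'   vectorized, need not be sorted for the closed-form path.
#' @param kinetics A [kinetic_params()] object.
#' @param roi One of `"cp"`, `"transition"`, `"rest_of_lv"`, `"cgm"`.
#' @return Concentration in mmol/L at each `t`.
#' @export
csf_concentration_curve <- function(t, kinetics,
                                    roi = c("cp", "transition",
                                            "rest_of_lv", "cgm")) {
  stopifnot(inherits(kinetics, "kinetic_params"))
  roi <- match.arg(roi)
  a <- kinetics$aif
  cp_curve <- function(tt) {
    if (kinetics$k_out == 0) {
      kinetics$bcsfb_transfer *
        .aif_integral(tt, a$peak, a$delay, a$shape, a$scale)
    } else {
      ord <- order(tt)
      ts <- tt[ord]
      dt <- diff(c(0, ts))
      if (any(kinetics$k_out * dt > 1)) {
        stop("explicit step unstable: k_out * dt > 1; refine the grid",
             call. = FALSE)
      }
      cin <- gamma_variate_aif(ts, a$peak, a$delay, a$shape, a$scale)
      cc <- numeric(length(ts))
      prev <- 0
      for (i in seq_along(ts)) {
        prev <- prev + dt[i] * (kinetics$bcsfb_transfer * cin[i] -
                                  kinetics$k_out * prev)
        cc[i] <- prev
      }
      cc[order(ord)]
    }
  }
  slow <- function(tt, plateau) {
    d <- kinetics$dispersion_to_lv
    norm <- 1 - exp(-(kinetics$t_4h - d$delay) / d$tau)
    plateau * pmax(1 - exp(-pmax(tt - d$delay, 0) / d$tau), 0) / norm
  }
  switch(roi,
         cp = cp_curve(t),
         rest_of_lv = slow(t, kinetics$plateau_c_lv_4h),
         cgm = slow(t, kinetics$cgm_scale * kinetics$plateau_c_lv_4h),
         transition = 0.5 * (cp_curve(t) + slow(t, kinetics$plateau_c_lv_4h)))
}

#' Geometry, noise and acquisition layout of the synthetic phantom
#'
#' Defines the voxel grid and ROI geometry (a ventricle ellipsoid holding
#' a central CP blob, its two-layer transition shell, perivascular cGM
#' shell, a corpus callosum block, and surrounding brain), the acquisition
#' timing (28 pre- and 32 post-injection frames at 10 s, plus a separate
#' 23-frame stationary series at 4 h), Rician noise level, per-session
#' scanner gains, and the seed.
#'
#' @param grid Integer vector of 3 grid dimensions.
#' @param voxel_volume Voxel volume in mm^3 (default 0.8 mm isotropic).
#' @param n_pre,n_post Frames before/after injection in the dynamic
#'   session.
#' @param n_4h Frames of the 4 h session.
#' @param frame_interval Frame spacing in seconds.
#' @param snr Signal-to-noise ratio of clean ventricular CSF signal to the
#'   per-channel Gaussian noise sigma; `Inf` for a noiseless phantom.
#' @param session_gains Named numeric, arbitrary scanner scale per session
#'   (`post`, `post_4h`); deliberately unequal so reference-region
#'   normalization is exercised.
#' @param cp_radius,ventricle_radii Geometry in voxels.
#' @param csf_fraction_cgm CSF volume fraction of perivascular cGM voxels.
#' @param csf_fraction_cc CSF volume fraction of corpus callosum voxels.
#' @param seed Integer seed; a fixed seed makes the rendered phantom
#'   byte-identical.
#' @return A `phantom_spec` object.
#' @export
phantom_spec <- function(grid = c(24, 24, 16), voxel_volume = 0.512,
                         n_pre = 28, n_post = 32, n_4h = 23,
                         frame_interval = 10, snr = 50,
                         session_gains = c(post = 1000, post_4h = 1300),
                         cp_radius = 2.3, ventricle_radii = c(6, 4.5, 4.5),
                         csf_fraction_cgm = 0.3, csf_fraction_cc = 0.1,
                         seed = 42L) {
  stopifnot(length(grid) == 3, all(grid >= 8), voxel_volume > 0,
            n_pre >= 3, n_post >= 1, n_4h >= 1, frame_interval > 0,
            snr > 0, cp_radius > 0, all(ventricle_radii > 0))
  structure(
    list(grid = as.integer(grid), voxel_volume = voxel_volume,
         n_pre = n_pre, n_post = n_post, n_4h = n_4h,
         frame_interval = frame_interval, snr = snr,
         session_gains = session_gains, cp_radius = cp_radius,
         ventricle_radii = ventricle_radii,
         csf_fraction_cgm = csf_fraction_cgm,
         csf_fraction_cc = csf_fraction_cc,
         seed = as.integer(seed)),
    class = "phantom_spec"
  )
}

# Build the label volume for a phantom_spec. Ellipsoids are centred on the
# grid; the CC block sits between ventricle and cGM shell; everything else
# inside the brain ellipsoid is generic parenchyma.
.phantom_labels <- function(spec) {
  g <- spec$grid
  ctr <- (g + 1) / 2
  ax <- lapply(1:3, function(i) seq_len(g[i]) - ctr[i])
  X <- array(rep(ax[[1]], times = g[2] * g[3]), g)
  Y <- array(rep(rep(ax[[2]], each = g[1]), times = g[3]), g)
  Z <- array(rep(ax[[3]], each = g[1] * g[2]), g)
  inside <- function(r) (X / r[1])^2 + (Y / r[2])^2 + (Z / r[3])^2 <= 1
  vent <- inside(spec$ventricle_radii)
  cp <- (X^2 + Y^2 + Z^2) <= spec$cp_radius^2
  if (any(cp & !vent)) stop("CP blob exceeds the ventricle; geometry invalid")
  trans <- transition_mask(cp, vent, layers = 2)
  rest <- vent & !cp & !trans
  brain_r <- pmin(g / 2 - 0.5, spec$ventricle_radii * 1.9)
  brain <- inside(brain_r)
  if (!any(brain & !vent)) stop("grid too small for brain shell")
  cgm <- inside(brain_r) & !inside(brain_r * 0.88) # outer cortical shell
  cc_half <- 3L
  ccx <- floor(ctr[1] + spec$ventricle_radii[1] + 1) +
    0:1
  ccx <- ccx[ccx <= g[1]]
  cc <- array(FALSE, g)
  cc[ccx,
     pmax(1, floor(ctr[2] - cc_half)):pmin(g[2], ceiling(ctr[2] + cc_half)),
     pmax(1, floor(ctr[3] - cc_half)):pmin(g[3], ceiling(ctr[3] + cc_half))] <- TRUE
  cc <- cc & brain & !vent & !cgm
  if (!any(cc)) stop("grid too small to place the reference block")
  lab <- array(0L, g)
  lab[brain] <- 6L
  lab[cgm] <- 4L
  lab[cc] <- 5L
  lab[rest] <- 3L
  lab[trans] <- 2L
  lab[cp] <- 1L
  lab
}

# Rician-corrupt a non-negative signal array: magnitude of (S + n1, n2)
# with independent Gaussian channels of sd sigma.
.rician <- function(s, sigma) {
  if (sigma == 0) return(s)
  n <- length(s)
  sqrt((s + stats::rnorm(n, 0, sigma))^2 + stats::rnorm(n, 0, sigma)^2)
}

#' Render the synthetic dynamic phantom
#'
#' Produces the full study fixture: the dynamic session (pre- and
#' post-injection frames), a stationary 4 h session, the label volume, and
#' the ground truth. Per frame, each region's programmed concentration
#' (at the frame midpoint) is pushed through the relaxivity and sequence
#' signal models; partial-volume regions (perivascular cGM, corpus
#' callosum) mix compartment signals by volume fraction, with parenchyma
#' contributing essentially nothing at the long echo time. Rician noise
#' with `sigma = gain * clean CSF signal / snr` is then applied per voxel.
#' A fixed seed yields identical output.
#'
#' @param spec A [phantom_spec()] object.
#' @param kinetics A [kinetic_params()] object.
#' @param seq A [cdsc_params()] object used for rendering.
#' @return A list: `series` (dynamic [dynamic_series()]), `series_4h`,
#'   `rois` ([roi_set()]), and `truth` (programmed concentrations and
#'   timings: `c_cp_plateau`, `c_lv_4h`, `c_cgm_4h`, `t_onset`, `ttp`
#'   derived from the clean CP curve on the frame grid).
#' @export
render_dynamic_series <- function(spec = phantom_spec(),
                                  kinetics = kinetic_params(),
                                  seq = cdsc_params()) {
  stopifnot(inherits(spec, "phantom_spec"), inherits(kinetics, "kinetic_params"))
  lab <- .phantom_labels(spec)
  rois <- roi_set(lab, spec$voxel_volume)
  tis <- list(csf = tissue_defaults("csf"), gm = tissue_defaults("gm"),
              wm = tissue_defaults("wm"))

  csf_sig <- function(c) {
    cdsc_signal(seq, t1_with_gd(tis$csf$T1_0, tis$csf$r1, c),
                t2_with_gd(tis$csf$T2_0, tis$csf$r2, c))
  }
  gm_sig <- cdsc_signal(seq, tis$gm$T1_0, tis$gm$T2_0)
  wm_sig <- cdsc_signal(seq, tis$wm$T1_0, tis$wm$T2_0)
  s_csf0 <- csf_sig(0)

  dip_factor <- function(t_rel) {
    d <- kinetics$dip
    if (is.null(d)) return(rep(1, length(t_rel)))
    1 - d$depth / 100 * exp(-(t_rel - d$center)^2 / (2 * (d$width / 2)^2))
  }

  # clean per-region signal (fraction of M0) at times t_rel post-injection
  region_signal <- function(region, t_rel) {
    switch(region,
      cp = csf_sig(csf_concentration_curve(t_rel, kinetics, "cp")) *
        dip_factor(t_rel),
      transition = csf_sig(csf_concentration_curve(t_rel, kinetics,
                                                   "transition")) *
        dip_factor(t_rel),
      rest_of_lv = csf_sig(csf_concentration_curve(t_rel, kinetics,
                                                   "rest_of_lv")),
      cgm = {
        comp <- voxel_composition(c(csf = spec$csf_fraction_cgm,
                                    gm = 1 - spec$csf_fraction_cgm))
        vapply(t_rel, function(tt) {
          voxel_signal(comp, c(
            csf = csf_sig(csf_concentration_curve(tt, kinetics, "cgm")),
            gm = gm_sig))
        }, numeric(1)) * dip_factor(t_rel)
      },
      cc = {
        comp <- voxel_composition(c(csf = spec$csf_fraction_cc,
                                    wm = 1 - spec$csf_fraction_cc))
        rep(voxel_signal(comp, c(csf = s_csf0, wm = wm_sig)), length(t_rel))
      },
      brain = rep(gm_sig, length(t_rel)))
  }

  render_session <- function(n_frames, t_rel_mid, gain) {
    sigma <- if (is.finite(spec$snr)) gain * s_csf0 / spec$snr else 0
    vol <- array(0, c(prod(spec$grid), n_frames))
    for (region in c("cp", "transition", "rest_of_lv", "cgm", "cc", "brain")) {
      idx <- as.vector(lab == .roi_codes[[region]])
      if (!any(idx)) next
      s <- gain * region_signal(region, t_rel_mid)
      vol[idx, ] <- rep(s, each = sum(idx))
    }
    vol[] <- .rician(vol, sigma)
    array(vol, c(spec$grid, n_frames))
  }

  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old_seed))
    assign(".Random.seed", old_seed, envir = globalenv()), add = TRUE)
  set.seed(spec$seed)

  dt <- spec$frame_interval
  n_dyn <- spec$n_pre + spec$n_post
  inj <- spec$n_pre * dt
  mid_rel <- (seq_len(n_dyn) - 0.5) * dt - inj          # pre frames negative
  dyn <- render_session(n_dyn, ifelse(mid_rel < 0, -1, mid_rel),
                        spec$session_gains[["post"]])
  series <- dynamic_series(dyn, dt, inj, "post")

  mid_4h <- kinetics$t_4h + (seq_len(spec$n_4h) - 0.5) * dt
  s4 <- render_session(spec$n_4h, mid_4h, spec$session_gains[["post_4h"]])
  series_4h <- dynamic_series(s4, dt, 0, "post_4h")

  # programmed timings from the clean CP curve on the frame-start grid
  t_grid <- (seq_len(spec$n_post) - 1) * dt
  c_grid <- csf_concentration_curve(t_grid + dt / 2, kinetics, "cp")
  plateau <- csf_concentration_curve(250, kinetics, "cp")
  t_on <- t_grid[which(c_grid > 0)[1]]
  ttp <- t_grid[which(c_grid >= 0.9 * plateau)[1]]

  list(series = series, series_4h = series_4h, rois = rois,
       truth = list(
         c_cp_plateau = kinetics$plateau_c_cp,
         c_lv_4h = kinetics$plateau_c_lv_4h,
         c_cgm_4h = kinetics$cgm_scale * kinetics$plateau_c_lv_4h,
         t_onset = t_on, ttp = ttp,
         snr = spec$snr, seed = spec$seed))
}

#' Write a rendered phantom to disk
#'
#' Writes `series.nii.gz`, `series_4h.nii.gz` and `labels.nii.gz`
#' (NIfTI-1) plus `truth.yaml` holding the ground truth and the timing
#' sidecar needed to reload the series.
#'
#' @param seed Integer seed forwarded to [phantom_spec()].
#' @param out_dir Output directory (created if absent).
#' @param spec,kinetics Overrides; `spec$seed` is replaced by `seed`.
#' @return Invisibly, the list returned by [render_dynamic_series()] with
#'   a `paths` element added.
#' @export
make_phantom <- function(seed = 42L, out_dir,
                         spec = phantom_spec(), kinetics = kinetic_params()) {
  spec$seed <- as.integer(seed)
  ph <- render_dynamic_series(spec, kinetics)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  paths <- list(
    series = file.path(out_dir, "series.nii.gz"),
    series_4h = file.path(out_dir, "series_4h.nii.gz"),
    labels = file.path(out_dir, "labels.nii.gz"),
    truth = file.path(out_dir, "truth.yaml"))
  RNifti::writeNifti(RNifti::asNifti(ph$series$data), paths$series)
  RNifti::writeNifti(RNifti::asNifti(ph$series_4h$data), paths$series_4h)
  RNifti::writeNifti(RNifti::asNifti(ph$rois$labels), paths$labels)
  yaml::write_yaml(c(ph$truth, list(
    frame_interval = ph$series$frame_interval,
    injection_time = ph$series$injection_time,
    voxel_volume = ph$rois$voxel_volume)), paths$truth)
  ph$paths <- paths
  invisible(ph)
}

#' Load a phantom written by [make_phantom()]
#'
#' @param dir Directory holding `series.nii.gz`, `series_4h.nii.gz`,
#'   `labels.nii.gz` and `truth.yaml`.
#' @return A list with `series`, `series_4h`, `rois`, `truth`.
#' @export
read_phantom <- function(dir) {
  truth <- yaml::read_yaml(file.path(dir, "truth.yaml"))
  dat <- array(RNifti::readNifti(file.path(dir, "series.nii.gz")),
               dim = dim(RNifti::readNifti(file.path(dir, "series.nii.gz"))))
  d4 <- RNifti::readNifti(file.path(dir, "series_4h.nii.gz"))
  lab <- RNifti::readNifti(file.path(dir, "labels.nii.gz"))
  list(
    series = dynamic_series(dat, truth$frame_interval, truth$injection_time,
                            "post"),
    series_4h = dynamic_series(array(d4, dim = dim(d4)),
                               truth$frame_interval, 0, "post_4h"),
    rois = roi_set(array(as.integer(round(lab)), dim = dim(lab)),
                   truth$voxel_volume),
    truth = truth)
}

#' Simulate a subject cohort table
#'
#' Draws a long-format cohort emulating the study's group structure for
#' the statistics layer: per subject, age (mean 48.9, SD 19.5 years,
#' truncated to 20-85), sex, weight (dose = 0.1 mmol/kg of body weight),
#' intracranial and lateral-ventricle volumes (LV volume drifts upward
#' with age), and per-ROI relative signal changes at the early and 4 h
#' sessions drawn around the programmed group set-points with
#' inter-subject spread; each subject's concentration is obtained by
#' inverting their own signal change (undefined for non-negative
#' changes), and onset/plateau times are drawn only where the early
#' change is reliably detectable (CP and transition), mirroring the
#' convention that timings are not estimated for non-significant changes.
#'
#' @param n Number of subjects.
#' @param seed Integer seed.
#' @param seq,tissue Model used for per-subject concentration inversion.
#' @return A data.frame with one row per subject x session x ROI:
#'   `subject`, `age`, `sex`, `weight`, `dose`, `icv`, `lv_volume`,
#'   `session`, `roi`, `delta_s`, `gd`, `t_onset`, `ttp`.
#' @export
simulate_cohort <- function(n = 25, seed = 42L,
                            seq = cdsc_params(),
                            tissue = tissue_defaults("csf")) {
  stopifnot(n >= 2)
  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old_seed))
    assign(".Random.seed", old_seed, envir = globalenv()), add = TRUE)
  set.seed(as.integer(seed))

  rtrunc <- function(n, mean, sd, lo, hi) {
    pmin(pmax(stats::rnorm(n, mean, sd), lo), hi)
  }
  age <- rtrunc(n, 48.9, 19.5, 20, 85)
  weight <- rtrunc(n, 75, 15, 45, 110)
  icv <- rtrunc(n, 1450, 130, 1100, 1800)
  lv_volume <- pmax(8 + 0.25 * (age - 48.9) + 0.012 * (icv - 1450) +
                      stats::rnorm(n, 0, 4), 3)
  subj <- data.frame(
    subject = sprintf("S%02d", seq_len(n)),
    age = age,
    sex = sample(c("F", "M"), n, replace = TRUE),
    weight = weight,
    dose = 0.1 * weight,
    icv = icv,
    lv_volume = lv_volume)

  # group set-points (mean, between-subject SD) per session x ROI
  setpts <- list(
    post = list(cp = c(-2.40, 1.5), transition = c(-0.53, 0.9),
                rest_of_lv = c(-0.18, 0.75), cgm = c(0.29, 1.05)),
    post_4h = list(cp = c(-7.86, 11.9), transition = c(-9.18, 12.7),
                   rest_of_lv = c(-7.58, 12.3), cgm = c(-7.86, 8.6)))
  rows <- list()
  for (session in names(setpts)) {
    for (roi in names(setpts[[session]])) {
      sp <- setpts[[session]][[roi]]
      ds <- stats::rnorm(n, sp[1], sp[2])
      gd <- vapply(ds, function(d) {
        if (d >= -0.01) return(NA_real_)
        tryCatch(estimate_concentration(d, seq, tissue)$c,
                 error = function(e) NA_real_)
      }, numeric(1))
      timed <- session == "post" && roi %in% c("cp", "transition")
      t_on <- if (timed) pmax(round(stats::rnorm(n, 20, 6) / 10) * 10, 10)
        else rep(NA_real_, n)
      ttp <- if (timed) pmax(round(stats::rnorm(n, 32, 12) / 10) * 10, t_on)
        else rep(NA_real_, n)
      rows[[paste(session, roi)]] <- cbind(
        subj, data.frame(session = session, roi = roi, delta_s = ds,
                         gd = gd, t_onset = t_on, ttp = ttp))
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
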