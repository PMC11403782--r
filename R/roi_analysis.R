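#' Dynamic 4D signal series
#'
#' Container for a dynamic acquisition: a 4D array `(x, y, z, t)` of
#' non-negative signal intensities with a constant frame interval and the
#' injection time. Frame `i` covers `[(i-1)*dt, i*dt)` from series start;
#' a frame belongs to a time window when its midpoint does, and the
#' injection is assumed to fall on a frame boundary.
#'
#' @param data 4D numeric array (x, y, z, t), non-negative.
#' @param frame_interval Frame spacing in seconds (> 0).
#' @param injection_time Injection time in seconds from series start; must
#'   lie within the series (use the series duration for a wholly
#'   pre-injection series and 0 for a wholly post-injection one).
#' @param session_label One of `"pre"`, `"post"`, `"post_4h"`.
#' @return A `dynamic_series` object.
#' @export
dynamic_series <- function(data, frame_interval, injection_time,
                           session_label = c("post", "pre", "post_4h")) {
  session_label <- match.arg(session_label)
  if (length(dim(data)) != 4) stop("data must be a 4D array", call. = FALSE)
  if (frame_interval <= 0) stop("frame_interval must be positive", call. = FALSE)
  dur <- dim(data)[4] * frame_interval
  if (injection_time < 0 || injection_time > dur) {
    stop("injection_time must lie within [0, series duration]", call. = FALSE)
  }
  if (any(data < 0)) stop("signal intensities must be non-negative", call. = FALSE)
  structure(
    list(data = data, frame_interval = frame_interval,
         injection_time = injection_time, session_label = session_label),
    class = "dynamic_series"
  )
}

#' @export
print.dynamic_series <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<dynamic_series> %s: %d x %d x %d, %d frames @ %gs, injection at %gs\n",
              x$session_label, d[1], d[2], d[3], d[4],
              x$frame_interval, x$injection_time))
  invisible(x)
}

# Frame midpoints in seconds from series start.
.frame_midpoints <- function(series) {
  (seq_len(dim(series$data)[4]) - 0.5) * series$frame_interval
}

#' Labeled region-of-interest set
#'
#' A single 3D integer label volume encoding the five analysis regions plus
#' background; a voxel belongs to at most one region so labels are disjoint
#' by construction. Codes: 0 background, 1 choroid plexus (`cp`), 2
#' transition shell (`transition`), 3 rest of the lateral ventricle
#' (`rest_of_lv`), 4 perivascular cortical gray matter (`cgm`), 5 corpus
#' callosum (`cc`), 6 other intracranial tissue (`brain`). The ventricle is
#' the union of codes 1-3; the intracranial volume is every non-background
#' voxel.
#'
#' @param labels 3D integer array of label codes.
#' @param voxel_volume Voxel volume in mm^3.
#' @return A `roi_set` object.
#' @export
roi_set <- function(labels, voxel_volume) {
  if (length(dim(labels)) != 3) stop("labels must be a 3D array", call. = FALSE)
  if (voxel_volume <= 0) stop("voxel_volume must be positive", call. = FALSE)
  codes <- sort(unique(as.integer(labels)))
  if (!all(codes %in% 0:6)) {
    stop("label codes must be integers in 0..6", call. = FALSE)
  }
  structure(list(labels = labels, voxel_volume = voxel_volume),
            class = "roi_set")
}

.roi_codes <- c(cp = 1L, transition = 2L, rest_of_lv = 3L,
                cgm = 4L, cc = 5L, brain = 6L)

#' Extract a binary mask from an ROI set
#'
#' @param rois A [roi_set()] object.
#' @param roi Region name: one of `"cp"`, `"transition"`, `"rest_of_lv"`,
#'   `"cgm"`, `"cc"`, `"brain"`, or the composites `"ventricle"` (cp +
#'   transition + rest of LV) and `"intracranial"` (all non-background).
#' @return A logical 3D array.
#' @export
roi_mask <- function(rois, roi) {
  stopifnot(inherits(rois, "roi_set"))
  lab <- rois$labels
  switch(roi,
         ventricle = lab %in% 1:3,
         intracranial = lab > 0L,
         {
           if (!roi %in% names(.roi_codes)) {
             stop("unknown ROI: ", roi, call. = FALSE)
           }
           lab == .roi_codes[[roi]]
         }) |> array(dim = dim(lab))
}

#' Ventricle and intracranial volumes of an ROI set
#'
#' @param rois A [roi_set()] object.
#' @return A list with `lv_volume` and `icv`, both in mL.
#' @export
roi_volumes <- function(rois) {
  list(
    lv_volume = sum(roi_mask(rois, "ventricle")) * rois$voxel_volume / 1000,
    icv = sum(roi_mask(rois, "intracranial")) * rois$voxel_volume / 1000
  )
}

# Shift a 3D logical array by one voxel along axis (+/-1), zero-filled.
.shift3d <- function(m, axis, dir) {
  out <- array(FALSE, dim(m))
  n <- dim(m)[axis]
  src <- if (dir > 0) 1:(n - 1) else 2:n
  dst <- if (dir > 0) 2:n else 1:(n - 1)
  idx_src <- list(TRUE, TRUE, TRUE); idx_src[[axis]] <- src
  idx_dst <- list(TRUE, TRUE, TRUE); idx_dst[[axis]] <- dst
  out[idx_dst[[1]], idx_dst[[2]], idx_dst[[3]]] <-
    m[idx_src[[1]], idx_src[[2]], idx_src[[3]]]
  out
}

# One binary dilation step at the given connectivity (6, 18 or 26).
.dilate3d <- function(m, connectivity = 6) {
  stopifnot(connectivity %in% c(6, 18, 26))
  out <- m
  shifts <- expand.grid(dx = -1:1, dy = -1:1, dz = -1:1)
  shifts <- shifts[!(shifts$dx == 0 & shifts$dy == 0 & shifts$dz == 0), ]
  ord <- abs(shifts$dx) + abs(shifts$dy) + abs(shifts$dz)
  keep <- switch(as.character(connectivity),
                 "6" = ord == 1, "18" = ord <= 2, "26" = ord <= 3)
  shifts <- shifts[keep, ]
  for (i in seq_len(nrow(shifts))) {
    s <- m
    if (shifts$dx[i] != 0) s <- .shift3d(s, 1, shifts$dx[i])
    if (shifts$dy[i] != 0) s <- .shift3d(s, 2, shifts$dy[i])
    if (shifts$dz[i] != 0) s <- .shift3d(s, 3, shifts$dz[i])
    out <- out | s
  }
  out
}

#' Transition shell around the choroid plexus
#'
#' Builds the transition region between the choroid plexus and open
#' ventricular CSF: the CP mask is dilated one voxel at a time, `layers`
#' times, each step clipped to the ventricle, and the CP itself is removed.
#' With the default face connectivity and an unconstrained interior this
#' yields the L1-distance shell `0 < |d|_1 <= layers`.
#'
#' @param cp_mask Logical 3D array, choroid plexus voxels; must lie inside
#'   `ventricle_mask`.
#' @param ventricle_mask Logical 3D array of the same dimensions.
#' @param layers Number of one-voxel dilation layers (default 2).
#' @param connectivity Neighborhood for one dilation step: 6 (faces, the
#'   default), 18 or 26.
#' @return Logical 3D array of transition voxels.
#' @export
transition_mask <- function(cp_mask, ventricle_mask, layers = 2,
                            connectivity = 6) {
  stopifnot(identical(dim(cp_mask), dim(ventricle_mask)),
            layers >= 0, layers == round(layers))
  cp_mask <- cp_mask != 0
  ventricle_mask <- ventricle_mask != 0
  if (any(cp_mask & !ventricle_mask)) {
    stop("choroid plexus mask must lie inside the ventricle mask", call. = FALSE)
  }
  grown <- cp_mask
  for (i in seq_len(layers)) {
    grown <- .dilate3d(grown, connectivity) & ventricle_mask
  }
  grown & !cp_mask
}

#' Reference-region (corpus callosum) normalization
#'
#' Divides every frame of a series by the session-wide mean signal inside
#' the reference mask. The corpus callosum shows essentially no
#' contrast-induced change over the experiment, so this removes
#' inter-session scanner gain differences; after normalization the
#' reference ROI mean over the session equals 1 and within-session relative
#' changes are untouched.
#'
#' @param series A [dynamic_series()] object.
#' @param cc_mask Logical 3D array, non-empty.
#' @return A new `dynamic_series` with normalized intensities.
#' @export
cc_normalize <- function(series, cc_mask) {
  stopifnot(inherits(series, "dynamic_series"))
  cc_mask <- cc_mask != 0
  if (!any(cc_mask)) stop("reference mask is empty", call. = FALSE)
  nt <- dim(series$data)[4]
  flat <- matrix(series$data, ncol = nt)
  m <- mean(flat[as.vector(cc_mask), , drop = FALSE])
  if (!is.finite(m) || m <= 0) {
    stop("reference-region mean is zero or non-finite; cannot normalize",
         call. = FALSE)
  }
  out <- series
  out$data <- series$data / m
  out
}

#' Per-frame relative signal change of an ROI
#'
#' Averages the signal over the whole ROI (no voxel selection) per frame
#' and expresses each frame as a percent change from the pre-injection
#' baseline: `100 * (S(t) - Sbar_pre) / Sbar_pre`, where `Sbar_pre` is the
#' mean over all frames whose midpoint precedes the injection.
#'
#' @param series A [dynamic_series()] object with at least 2 pre-injection
#'   frames.
#' @param mask Logical 3D array, non-empty.
#' @return A `delta_s_series` object: list with `time` (frame start times
#'   in seconds relative to injection), `delta_s` (percent per frame),
#'   `baseline_mean`, `baseline_sd` (of the pre-injection percent values),
#'   `n_baseline`, `frame_interval`.
#' @export
roi_delta_s <- function(series, mask) {
  stopifnot(inherits(series, "dynamic_series"))
  mask <- mask != 0
  if (!any(mask)) stop("ROI mask is empty", call. = FALSE)
  nt <- dim(series$data)[4]
  flat <- matrix(series$data, ncol = nt)
  roi_mean <- colMeans(flat[as.vector(mask), , drop = FALSE])
  mid <- .frame_midpoints(series)
  pre <- mid < series$injection_time
  if (sum(pre) < 2) {
    stop("need at least 2 pre-injection frames for a baseline", call. = FALSE)
  }
  s_pre <- mean(roi_mean[pre])
  if (s_pre <= 0) stop("non-positive baseline signal", call. = FALSE)
  delta <- 100 * (roi_mean - s_pre) / s_pre
  structure(
    list(time = (seq_len(nt) - 1) * series$frame_interval - series$injection_time,
         delta_s = delta,
         baseline_mean = s_pre,
         baseline_sd = stats::sd(delta[pre]),
         n_baseline = sum(pre),
         frame_interval = series$frame_interval),
    class = "delta_s_series"
  )
}

# Frames whose midpoint lies in [window[1], window[2]] seconds
# post-injection.
.window_frames <- function(ds, window) {
  mid <- ds$time + ds$frame_interval / 2
  mid >= window[1] & mid <= window[2]
}

#' Windowed mean of a relative signal change series
#'
#' Averages the per-frame percent change over frames whose midpoints fall
#' inside a post-injection window, by default 50-250 s. The early bolus
#' phase (0-50 s, where a transient dip can occur) never contributes with
#' the default window.
#'
#' @param ds A `delta_s_series` from [roi_delta_s()].
#' @param window Two-element numeric, seconds post-injection.
#' @return Mean percent change over the window.
#' @export
window_mean <- function(ds, window = c(50, 250)) {
  stopifnot(inherits(ds, "delta_s_series"),
            length(window) == 2, window[1] < window[2])
  inw <- .window_frames(ds, window)
  if (!any(inw)) {
    stop("no frames fall inside the requested window", call. = FALSE)
  }
  mean(ds$delta_s[inw])
}

#' Onset time of the contrast-induced signal change
#'
#' The first post-injection time (frame start, seconds after injection) at
#' which the series begins a run of at least `run_length` consecutive
#' frames whose change exceeds `z_thresh` baseline standard deviations in
#' the expected direction (negative for the CSF-selective sequence).
#' Returns `NA` when no such run exists, mirroring the convention that
#' onset is not estimated for non-significant changes.
#'
#' @param ds A `delta_s_series` with at least 3 baseline frames.
#' @param z_thresh Threshold in baseline SD units (default 2).
#' @param run_length Required consecutive supra-threshold frames (default 3).
#' @param direction `-1` (default) for a negative-going change, `+1` for
#'   positive.
#' @return Onset time in seconds post-injection, or `NA_real_`.
#' @export
onset_time <- function(ds, z_thresh = 2, run_length = 3, direction = -1) {
  stopifnot(inherits(ds, "delta_s_series"))
  if (ds$n_baseline < 3) {
    stop("need at least 3 baseline frames to estimate the baseline SD",
         call. = FALSE)
  }
  post <- ds$time >= 0
  x <- direction * ds$delta_s[post]
  t_post <- ds$time[post]
  hit <- x > z_thresh * ds$baseline_sd
  if (length(hit) < run_length) return(NA_real_)
  runs <- rle(hit)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1
  ok <- which(runs$values & runs$lengths >= run_length)
  if (!length(ok)) return(NA_real_)
  t_post[starts[ok[1]]]
}

#' Time to plateau of the contrast-induced signal change
#'
#' The first post-onset time (frame start, seconds after injection) at
#' which the change reaches `plateau_fraction` of the plateau level, where
#' the plateau level is the median change over the summary window (a
#' robust choice unaffected by any early bolus dip). Undefined (`NA`)
#' whenever the onset is undefined.
#'
#' @inheritParams onset_time
#' @param plateau_fraction Fraction of the plateau level to reach
#'   (default 0.9).
#' @param window Window defining the plateau level, seconds post-injection.
#' @return Time to plateau in seconds post-injection, or `NA_real_`.
#' @export
time_to_plateau <- function(ds, plateau_fraction = 0.9, window = c(50, 250),
                            z_thresh = 2, run_length = 3, direction = -1) {
  stopifnot(inherits(ds, "delta_s_series"),
            plateau_fraction > 0, plateau_fraction <= 1)
  t_on <- onset_time(ds, z_thresh = z_thresh, run_length = run_length,
                     direction = direction)
  if (is.na(t_on)) return(NA_real_)
  inw <- .window_frames(ds, window)
  if (!any(inw)) stop("no frames in the plateau window", call. = FALSE)
  plateau <- stats::median(ds$delta_s[inw])
  sel <- ds$time >= t_on
  x <- direction * ds$delta_s[sel]
  reached <- x >= plateau_fraction * direction * plateau
  if (!any(reached)) return(NA_real_)
  ds$time[sel][which(reached)[1]]
}

#' Amount of contrast agent in the lateral ventricle
#'
#' The product of a concentration and the ventricular volume:
#' mmol/L x mL = micromol.
#'
#' @param c Concentration in mmol/L (>= 0).
#' @param lv_volume Lateral ventricle volume in mL (>= 0).
#' @return Amount in micromol.
#' @export
lv_gd_amount <- function(c, lv_volume) {
  stopifnot(all(c >= 0), all(lv_volume >= 0))
  c * lv_volume
}

#' Full per-ROI analysis of a dynamic session
#'
#' Runs the ROI pipeline on one dynamic series: reference-region
#' normalization (optional; within-session relative changes are invariant
#' to it), per-ROI relative signal change, windowed summary, onset and
#' plateau timing, and inversion of the windowed change to a gadolinium
#' concentration when the change is negative. A positive windowed change
#' (no attainable concentration under the model) yields `NA` for the
#' concentration, and timings are `NA` when no significant run exists.
#'
#' @param series A [dynamic_series()] object.
#' @param rois A [roi_set()] object on the same voxel grid.
#' @param roi_names Regions to analyze.
#' @param window Summary window, seconds post-injection.
#' @param seq,tissue Model used for concentration inversion; defaults to
#'   the packaged long-TE sequence and CSF parameters.
#' @param normalize Apply [cc_normalize()] first (default TRUE).
#' @param z_thresh,run_length,plateau_fraction Timing-rule parameters, see
#'   [onset_time()] and [time_to_plateau()].
#' @return A data.frame with one row per ROI: `roi`, `delta_s` (windowed
#'   mean, percent), `baseline_sd` (percent), `gd` (mmol/L or `NA`),
#'   `t_onset`, `ttp` (seconds or `NA`), `n_voxels`.
#' @export
analyze_series <- function(series, rois,
                           roi_names = c("cp", "transition", "rest_of_lv", "cgm"),
                           window = c(50, 250),
                           seq = cdsc_params(),
                           tissue = tissue_defaults("csf"),
                           normalize = TRUE,
                           z_thresh = 2, run_length = 3,
                           plateau_fraction = 0.9) {
  stopifnot(inherits(series, "dynamic_series"), inherits(rois, "roi_set"))
  if (normalize) series <- cc_normalize(series, roi_mask(rois, "cc"))
  rows <- lapply(roi_names, function(rn) {
    m <- roi_mask(rois, rn)
    ds <- roi_delta_s(series, m)
    wm <- window_mean(ds, window)
    gd <- if (wm < 0) {
      tryCatch(estimate_concentration(wm, seq, tissue)$c,
               error = function(e) NA_real_)
    } else NA_real_
    data.frame(
      roi = rn,
      delta_s = wm,
      baseline_sd = ds$baseline_sd,
      gd = gd,
      t_onset = onset_time(ds, z_thresh, run_length),
      ttp = time_to_plateau(ds, plateau_fraction, window, z_thresh, run_length),
      n_voxels = sum(m)
    )
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Cross-session relative signal change (delayed time point)
#'
#' Compares a later session (e.g. 4 h post-injection) against the
#' pre-injection baseline of the first session. Both series are
#' reference-normalized with their own session-wide corpus callosum mean,
#' which removes the inter-session gain difference; the change is then
#' `100 * (mean_late - mean_pre) / mean_pre` per ROI, and negative changes
#' are inverted to concentrations.
#'
#' @param baseline_series The first session ([dynamic_series()]); its
#'   pre-injection frames define the baseline.
#' @param late_series The delayed session; all frames are used.
#' @param rois A [roi_set()] shared by both sessions.
#' @param roi_names Regions to analyze.
#' @param seq,tissue Model used for concentration inversion.
#' @param normalize Apply [cc_normalize()] to both sessions (default TRUE).
#' @return A data.frame with `roi`, `delta_s` (percent), `gd` (mmol/L or
#'   `NA`).
#' @export
cross_session_delta_s <- function(baseline_series, late_series, rois,
                                  roi_names = c("cp", "transition",
                                                "rest_of_lv", "cgm"),
                                  seq = cdsc_params(),
                                  tissue = tissue_defaults("csf"),
                                  normalize = TRUE) {
  stopifnot(inherits(baseline_series, "dynamic_series"),
            inherits(late_series, "dynamic_series"),
            inherits(rois, "roi_set"))
  if (normalize) {
    cc <- roi_mask(rois, "cc")
    baseline_series <- cc_normalize(baseline_series, cc)
    late_series <- cc_normalize(late_series, cc)
  }
  mid <- .frame_midpoints(baseline_series)
  pre <- mid < baseline_series$injection_time
  if (sum(pre) < 2) {
    stop("need at least 2 pre-injection frames in the baseline session",
         call. = FALSE)
  }
  rows <- lapply(roi_names, function(rn) {
    m <- as.vector(roi_mask(rois, rn) != 0)
    if (!any(m)) stop("ROI mask is empty: ", rn, call. = FALSE)
    base_flat <- matrix(baseline_series$data, ncol = dim(baseline_series$data)[4])
    late_flat <- matrix(late_series$data, ncol = dim(late_series$data)[4])
    s_pre <- mean(colMeans(base_flat[m, , drop = FALSE])[pre])
    s_late <- mean(colMeans(late_flat[m, , drop = FALSE]))
    d <- 100 * (s_late - s_pre) / s_pre
    gd <- if (d < 0) {
      tryCatch(estimate_concentration(d, seq, tissue)$c,
               error = function(e) NA_real_)
    } else NA_real_
    data.frame(roi = rn, delta_s = d, gd = gd)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
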