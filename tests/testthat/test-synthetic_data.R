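test_that("gamma-variate input function has the stated shape", {
  # zero before the delay
  expect_identical(gamma_variate_aif(c(0, 10, 19.99)), rep(0, 3))
  # peak value ~1 mmol/L at t0 + shape*scale
  tt <- seq(0, 120, by = 0.01)
  v <- gamma_variate_aif(tt)
  expect_equal(max(v), 1, tolerance = 1e-6)
  expect_equal(tt[which.max(v)], 20 + 1 * 2.4, tolerance = 0.02)
  # integral finite, positive, and matching quadrature
  I <- stats::integrate(gamma_variate_aif, 0, Inf)$value
  expect_gt(I, 0)
  expect_equal(gadcsf:::.aif_integral(Inf, 1, 20, 1, 2.4), I,
               tolerance = 1e-6)
  expect_error(gamma_variate_aif(10, shape = -1), "positive")
})

test_that("programmed concentration curves hit their set-points", {
  kin <- kinetic_params()
  # no transfer -> identically zero
  kin0 <- kinetic_params(bcsfb_transfer = 0)
  expect_identical(csf_concentration_curve(c(0, 50, 250), kin0, "cp"),
                   rep(0, 3))
  # CP plateaus at the programmed value once the bolus has passed
  expect_equal(csf_concentration_curve(250, kin, "cp"), 0.027,
               tolerance = 1e-4)
  # rest of LV: near zero during the early window, exact plateau at 4 h
  expect_lt(csf_concentration_curve(250, kin, "rest_of_lv"), 0.002)
  expect_equal(csf_concentration_curve(14400, kin, "rest_of_lv"), 0.050,
               tolerance = 1e-12)
  # closed-form uptake equals quadrature of the input function
  for (t in c(25, 30, 60)) {
    manual <- kin$bcsfb_transfer *
      stats::integrate(gamma_variate_aif, 0, t)$value
    expect_equal(csf_concentration_curve(t, kin, "cp"), manual,
                 tolerance = 1e-6)
  }
})

test_that("clearance path integrates the kinetics like an independent solver", {
  skip_if_not_installed("deSolve")
  kin <- kinetic_params(bcsfb_transfer = 0.004, k_out = 0.005)
  tt <- seq(0, 300, by = 2)
  mine <- csf_concentration_curve(tt, kin, "cp")
  sol <- deSolve::ode(
    y = c(C = 0), times = tt,
    func = function(t, y, p) {
      list(0.004 * gamma_variate_aif(t) - 0.005 * y)
    }, parms = NULL)
  # explicit Euler on a 2 s grid vs adaptive solver
  expect_equal(mine, unname(sol[, "C"]), tolerance = 0.05)
  # unstable explicit step is refused
  kin_bad <- kinetic_params(bcsfb_transfer = 0.004, k_out = 0.5)
  expect_error(csf_concentration_curve(c(0, 100), kin_bad, "cp"),
               "unstable")
})

test_that("noiseless phantom renders exactly the model signals", {
  spec <- phantom_spec(snr = Inf, seed = 1L)
  ph <- render_dynamic_series(spec)
  m <- roi_mask(ph$rois, "cp")
  flat <- matrix(ph$series$data, ncol = dim(ph$series$data)[4])
  roi_mean <- colMeans(flat[as.vector(m), ])
  # every CP voxel identical (no noise) and the last pre frame equals the
  # clean zero-concentration CSF signal times the session gain
  s0 <- cdsc_signal(cdsc_params(), 4310, 1400) * 1000
  expect_equal(unname(roi_mean[28]), s0, tolerance = 1e-12)
  # post-plateau frame matches the forward model at the programmed level
  c_plateau <- csf_concentration_curve(315, kinetic_params(), "cp")
  s_pl <- cdsc_signal(cdsc_params(),
                      t1_with_gd(4310, 2.8, c_plateau),
                      t2_with_gd(1400, 3.4, c_plateau)) * 1000
  expect_equal(unname(roi_mean[60]), s_pl, tolerance = 1e-10)
})

test_that("phantom is reproducible under a fixed seed", {
  a <- render_dynamic_series(phantom_spec(seed = 9L))
  b <- render_dynamic_series(phantom_spec(seed = 9L))
  d <- render_dynamic_series(phantom_spec(seed = 10L))
  expect_identical(a$series$data, b$series$data)
  expect_identical(a$series_4h$data, b$series_4h$data)
  expect_false(identical(a$series$data, d$series$data))
  # rendering does not disturb the caller's RNG stream
  set.seed(123); x1 <- runif(1)
  set.seed(123); invisible(render_dynamic_series(phantom_spec(seed = 2L)))
  x2 <- runif(1)
  expect_identical(x1, x2)
})

test_that("phantom geometry satisfies the ROI invariants", {
  ph <- render_dynamic_series(phantom_spec(snr = Inf, seed = 1L))
  lab <- ph$rois$labels
  cp <- roi_mask(ph$rois, "cp")
  tr <- roi_mask(ph$rois, "transition")
  vent <- roi_mask(ph$rois, "ventricle")
  expect_true(all(tr <= vent))                      # transition inside LV
  expect_identical(sum(cp & tr), 0L)                # disjoint
  expect_identical(roi_mask(ph$rois, "rest_of_lv"),
                   vent & !cp & !tr)
  # transition is the two-layer shell of the CP inside the ventricle
  expect_identical(tr, transition_mask(cp, vent, layers = 2))
  vols <- roi_volumes(ph$rois)
  expect_gt(vols$icv, vols$lv_volume)
})

test_that("Rician magnitude noise has small ROI-mean bias above SNR 10", {
  set.seed(77)
  s <- rep(1, 2e5)
  for (snr in c(10, 50)) {
    m <- gadcsf:::.rician(s, 1 / snr)
    expect_lt(abs(mean(m) - 1), 0.01)       # < 1% bias
  }
  # noiseless passthrough is exact
  expect_identical(gadcsf:::.rician(s, 0), s)
})

test_that("phantom round-trips through NIfTI on disk", {
  dir <- file.path(tempdir(), "ph-roundtrip")
  ph <- make_phantom(seed = 4L, out_dir = dir,
                     spec = phantom_spec(grid = c(16, 16, 12), seed = 4L))
  rt <- read_phantom(dir)
  expect_equal(rt$series$data, unclass(ph$series$data), tolerance = 1e-12,
               ignore_attr = TRUE)
  expect_identical(rt$rois$labels, array(as.integer(ph$rois$labels),
                                         dim(ph$rois$labels)))
  expect_equal(rt$truth$c_lv_4h, ph$truth$c_lv_4h)
  expect_identical(rt$series$injection_time, ph$series$injection_time)
})

test_that("simulated cohort carries the dose rule and set-point structure", {
  co <- simulate_cohort(n = 40, seed = 8L)
  expect_equal(co$dose, 0.1 * co$weight)
  expect_false(anyDuplicated(co$subject[co$session == "post" &
                                          co$roi == "cp"]) > 0)
  cp <- co[co$session == "post" & co$roi == "cp", ]
  # group mean near the set-point (3 SE slack at SD 1.5)
  expect_lt(abs(mean(cp$delta_s) + 2.40), 3 * 1.5 / sqrt(40))
  # inversion consistency: each defined concentration reproduces the
  # subject's own signal change
  ok <- which(!is.na(cp$gd))[1:5]
  for (i in ok) {
    expect_equal(forward_delta_s(cp$gd[i], cdsc_params(),
                                 tissue_defaults("csf")),
                 cp$delta_s[i], tolerance = 1e-5)
  }
  # timings only where the early change is detectable
  expect_true(all(is.na(co$t_onset[co$roi == "cgm"])))
  expect_true(all(!is.na(co$t_onset[co$session == "post" & co$roi == "cp"])))
})
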