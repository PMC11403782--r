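test_that("transition shell equals the brute-force L1-ball oracle", {
  # centered CP voxel in a 7x7x7 ventricle block: |d|_1 <= 2 shell has
  # 6 + 18 = 24 voxels
  vent <- array(TRUE, c(7, 7, 7))
  cp <- array(FALSE, c(7, 7, 7)); cp[4, 4, 4] <- TRUE
  tm <- transition_mask(cp, vent, layers = 2)
  expect_identical(sum(tm), 24L)
  expect_identical(tm, oracle_transition_l1(cp, vent, 2))

  # layers = 0 -> empty
  expect_identical(sum(transition_mask(cp, vent, layers = 0)), 0L)

  # CP in a corner: clipped by the ventricle boundary, fewer than 24
  cp2 <- array(FALSE, c(7, 7, 7)); cp2[1, 1, 1] <- TRUE
  tm2 <- transition_mask(cp2, vent, layers = 2)
  expect_lt(sum(tm2), 24)
  expect_identical(tm2, oracle_transition_l1(cp2, vent, 2))

  # randomized convex-ventricle cases against the oracle
  set.seed(11)
  for (i in 1:5) {
    d <- c(6, 6, 6)
    vent_i <- array(FALSE, d)
    vent_i[2:5, 2:5, 2:5] <- TRUE
    cp_i <- array(FALSE, d)
    pts <- cbind(sample(3:4, 2, TRUE), sample(3:4, 2, TRUE),
                 sample(3:4, 2, TRUE))
    cp_i[pts] <- TRUE
    L <- sample(1:3, 1)
    expect_identical(transition_mask(cp_i, vent_i, layers = L),
                     oracle_transition_l1(cp_i, vent_i, L))
  }

  # CP outside ventricle is an error
  bad_vent <- vent; bad_vent[4, 4, 4] <- FALSE
  expect_error(transition_mask(cp, bad_vent), "inside")
})

test_that("reference-region normalization removes session gain", {
  set.seed(3)
  base <- array(abs(rnorm(8 * 5, 100, 5)), c(2, 2, 2, 5))
  s1 <- dynamic_series(base, 10, 20)
  s2 <- dynamic_series(3 * base, 10, 20)
  cc <- array(FALSE, c(2, 2, 2)); cc[1, , ] <- TRUE
  n1 <- cc_normalize(s1, cc)
  n2 <- cc_normalize(s2, cc)
  expect_equal(n1$data, n2$data, tolerance = 1e-12)
  # session-wide reference mean is 1 after normalization
  expect_equal(mean(matrix(n1$data, ncol = 5)[as.vector(cc), ]), 1)
  # two sessions with different gains but identical underlying dynamics
  # give identical relative changes after normalization
  m <- full_mask()
  expect_equal(roi_delta_s(n1, m)$delta_s, roi_delta_s(n2, m)$delta_s,
               tolerance = 1e-12)
  expect_error(cc_normalize(s1, array(FALSE, c(2, 2, 2))), "empty")
})

test_that("relative signal change follows its definition exactly", {
  # constant series -> all zeros
  s_const <- series_from_values(rep(100, 10), 10, 40)
  expect_equal(roi_delta_s(s_const, full_mask())$delta_s, rep(0, 10))
  # baseline 100, post frames at 92.42 -> -7.58% each
  v <- c(rep(100, 4), rep(92.42, 6))
  ds <- roi_delta_s(series_from_values(v, 10, 40), full_mask())
  expect_equal(ds$delta_s[5:10], rep(-7.58, 6), tolerance = 1e-10)
  expect_equal(ds$baseline_mean, 100)
  expect_identical(ds$n_baseline, 4L)
  expect_error(roi_delta_s(series_from_values(v, 10, 40),
                           array(FALSE, c(2, 2, 2))), "empty")
  expect_error(roi_delta_s(series_from_values(v, 10, 10), full_mask()),
               "baseline")
})

test_that("windowed mean uses midpoints and excludes the bolus dip", {
  # constant -2.4% after injection
  v <- c(rep(100, 5), rep(97.6, 30))
  ds <- roi_delta_s(series_from_values(v, 10, 50), full_mask())
  expect_equal(window_mean(ds), -2.4, tolerance = 1e-10)
  # a -10% dip at 20-30 s then a -2.4% plateau: dip frames fall outside
  # the 50-250 s window and never contribute
  v2 <- rep(100, 35)
  t_mid <- (seq_along(v2) - 0.5) * 10 - 50       # relative to injection
  v2[t_mid > 0] <- 97.6
  v2[t_mid > 20 & t_mid < 30] <- 90
  ds2 <- roi_delta_s(series_from_values(v2, 10, 50), full_mask())
  expect_equal(window_mean(ds2), -2.4, tolerance = 1e-10)
  # window beyond the series is an error
  expect_error(window_mean(ds, c(400, 600)), "window")
})

test_that("onset detection finds steps, ignores noise-only series", {
  # noiseless step at t = 20 s post-injection
  v <- rep(100, 40); t0 <- 100
  tt <- (seq_along(v) - 1) * 10 - t0
  v[tt >= 20] <- 98
  ds <- roi_delta_s(series_from_values(v, 10, t0), full_mask())
  expect_identical(onset_time(ds), 20)
  expect_identical(time_to_plateau(ds), 20)   # step: plateau at onset
  # pure-noise series: undefined
  set.seed(5)
  vn <- 100 + rnorm(40)
  dsn <- roi_delta_s(series_from_values(vn, 10, t0), full_mask())
  expect_true(is.na(onset_time(dsn)))
  expect_true(is.na(time_to_plateau(dsn)))
  # fewer than 3 baseline frames is an error
  ds2 <- roi_delta_s(series_from_values(v, 10, 20), full_mask())
  expect_error(onset_time(ds2), "baseline")
})

test_that("time to plateau on a linear ramp matches the closed form", {
  # 1 s frames; ramp from 0 at 20 s to -10% at 40 s, then flat; the 0.9
  # plateau fraction is reached at 38 s
  t0 <- 30
  n <- 300
  mid <- (seq_len(n) - 0.5) * 1 - t0
  delta <- pmin(pmax((mid - 20) / 20, 0), 1) * -10
  v <- 100 * (1 + delta / 100)
  ds <- roi_delta_s(series_from_values(v, 1, t0), full_mask())
  expect_identical(onset_time(ds), 20)
  expect_identical(time_to_plateau(ds), 38)
})

test_that("ventricular amount is the concentration-volume product", {
  expect_equal(lv_gd_amount(0.05, 20), 1.0)
  expect_identical(lv_gd_amount(0, 123), 0)
  expect_equal(lv_gd_amount(0.03, 40), 2 * lv_gd_amount(0.03, 20))
  expect_error(lv_gd_amount(-1, 10), class = "simpleError")
})
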