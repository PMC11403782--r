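test_that("relaxivity model reproduces published post-contrast CSF values", {
  # CSF at 0.2 mmol/L: published rounded values 1262 / 717 ms
  expect_equal(t1_with_gd(4310, 2.8, 0.2), 1262.60, tolerance = 1e-4)
  expect_equal(t2_with_gd(1400, 3.4, 0.2), 717.21, tolerance = 1e-4)
  # identity at zero concentration
  expect_identical(t1_with_gd(4310, 2.8, 0), 4310)
  expect_identical(t2_with_gd(1400, 3.4, 0), 1400)
  # blood at 1 mmol/L from the equations (the published blood+Gd pair is
  # known to be mutually inconsistent with the equations; these are the
  # computed values)
  expect_equal(t1_with_gd(1878, 4.4, 1.0), oracle_t1gd(1878, 4.4, 1.0))
  expect_equal(t1_with_gd(1878, 4.4, 1.0), 202.74, tolerance = 1e-4)
  expect_equal(t2_with_gd(157, 5.5, 1.0), 84.25, tolerance = 1e-3)
})

test_that("gadolinium-shortened relaxation is decreasing and convex in c", {
  c_grid <- seq(0, 2, length.out = 101)
  for (f in list(function(c) t1_with_gd(4310, 2.8, c),
                 function(c) t2_with_gd(1400, 3.4, c))) {
    v <- f(c_grid)
    expect_true(all(diff(v) < 0))
    expect_true(all(diff(diff(v)) > 0))   # convex
    expect_true(all(v <= f(0)))
  }
  expect_error(t1_with_gd(-1, 2.8, 0.1), "positive")
  expect_error(t1_with_gd(4310, 2.8, -0.1), "non-negative")
  expect_error(t2_with_gd(1400, -3.4, 0.1), "non-negative")
})

test_that("long-TE sequence signal matches the closed form and suppresses blood", {
  seq <- cdsc_params()
  expect_equal(cdsc_signal(seq, 4310, 1400), oracle_cdsc(4310, 1400))
  expect_equal(cdsc_signal(seq, 4310, 1400), 0.3018, tolerance = 1e-3)
  # blood: T2 = 157 ms at TE = 1347 ms leaves < 0.1% of equilibrium signal
  expect_lt(cdsc_signal(seq, 1878, 157), 1e-3)
  expect_equal(cdsc_signal(seq, 1878, 157), 1.8e-4, tolerance = 2e-2)
  # parenchyma even more suppressed
  expect_lt(cdsc_signal(seq, 1607, 63), 1e-6)
  # limits: negligible TE, TR much longer than T1 -> full recovery
  s_lim <- cdsc_signal(cdsc_params(TR = 1e6, TE = 1e-6, echo_spacing = 1,
                                   etl = 1), 100, 1400)
  expect_equal(s_lim, 1.0, tolerance = 1e-6)
  expect_error(cdsc_params(TR = 3000, TE = 1347, echo_spacing = 3.2,
                           etl = 1024), "echo-train")
  expect_error(cdsc_signal(flair_params(), 4310, 1400), "cdsc")
})

test_that("FLAIR nulls pre-contrast CSF and enhances gadolinium-laden CSF", {
  seq <- flair_params()
  expect_equal(flair_signal(seq, 4310, 1400), oracle_flair(4310, 1400))
  # CSF null: |signal| < 0.01 pre-contrast
  expect_lt(abs(flair_signal(seq, 4310, 1400)), 0.01)
  expect_equal(flair_signal(seq, 4310, 1400), -0.0079, tolerance = 2e-2)
  # positive enhancement at 0.2 mmol/L
  s_gd <- flair_signal(seq, t1_with_gd(4310, 2.8, 0.2),
                       t2_with_gd(1400, 3.4, 0.2))
  expect_equal(s_gd, 0.466, tolerance = 1e-3)
  # positive over the low-concentration range
  for (c in seq(0.05, 0.5, by = 0.05)) {
    expect_gt(flair_signal(seq, t1_with_gd(4310, 2.8, c),
                           t2_with_gd(1400, 3.4, c)), 0)
  }
  # instantaneous-recovery limit: signal -> exp(-TE/T2)
  expect_equal(flair_signal(seq, 1e-6, 1400), exp(-180 / 1400),
               tolerance = 1e-9)
  expect_error(flair_params(TR = 1500, TI = 2000), "TI")
})

test_that("voxel mixing is a fraction-weighted sum with validated input", {
  s <- c(csf = 0.3018, blood = 1.8e-4)
  expect_identical(voxel_signal(voxel_composition(c(csf = 1)), s),
                   s[["csf"]])
  expect_equal(voxel_signal(voxel_composition(c(csf = 0.5, blood = 0.5)), s),
               0.1510, tolerance = 1e-3)
  expect_error(voxel_composition(c(csf = 0.5, blood = 0.4)), "sum to 1")
  expect_error(voxel_composition(c(csf = 1.2, blood = -0.2)), "\\[0, 1\\]")
  expect_error(voxel_signal(voxel_composition(c(csf = 0.5, gm = 0.5)),
                            c(csf = 0.3)), "gm")
})

test_that("contrast curves match pointwise brute-force recomputation", {
  csf <- tissue_defaults("csf")
  grid <- seq(0, 1, length.out = 41)
  cc <- contrast_curve(cdsc_params(), csf, grid)
  manual <- vapply(grid, function(c) {
    abs(oracle_cdsc(oracle_t1gd(4310, 2.8, c), oracle_t2gd(1400, 3.4, c))) -
      abs(oracle_cdsc(4310, 1400))
  }, numeric(1))
  expect_equal(cc$delta, manual, tolerance = 1e-12)
  expect_identical(cc$delta[1], 0)

  fl <- contrast_curve(flair_params(), csf, grid)
  manual_fl <- vapply(grid, function(c) {
    abs(oracle_flair(oracle_t1gd(4310, 2.8, c), oracle_t2gd(1400, 3.4, c))) -
      abs(oracle_flair(4310, 1400))
  }, numeric(1))
  expect_equal(fl$delta, manual_fl, tolerance = 1e-12)

  # baseline convention matches the measured relative-change definition
  cb <- contrast_curve(cdsc_params(), csf, c(0, 0.0501),
                       normalize = "baseline")
  expect_equal(100 * cb$delta[2], -7.59, tolerance = 1e-3)

  # blood contrast is minimal at every concentration under the long TE
  blood <- tissue_defaults("blood")
  bc <- contrast_curve(cdsc_params(), blood, seq(0, 2, length.out = 81))
  expect_true(all(abs(bc$delta) < 1e-3))

  expect_error(contrast_curve(cdsc_params(), csf, c(0.2, 0.1)), "ascending")
  expect_error(contrast_curve(cdsc_params(), csf, c(-0.1, 0.1)),
               "non-negative")
})
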