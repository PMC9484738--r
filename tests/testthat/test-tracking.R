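make_speckle_frame <- function(seed = 1, ns = 400, nl = 24) {
  set.seed(seed)
  spec <- transducer_spec(n_lines = nl, aperture_mm = nl * 0.3)
  f <- make_scatterer_field(c(nl * 0.3, ns * stpe:::axial_sample_mm(spec)),
                            10, seed = seed, spec = spec)
  list(rf = synthesize_rf(f, spec, snr_db = Inf), field = f, spec = spec)
}

test_that("dynamic programming finds exact integer shifts", {
  fx <- make_speckle_frame(1)
  pre <- fx$rf
  # identical frames: zero displacement
  d0 <- dp_integer_displacement(pre, pre, c(5, 1))
  expect_true(all(d0$da == 0))
  expect_true(all(d0$dl == 0))
  # pure 7-sample axial shift (pattern moved 7 samples deeper):
  # post[x + 7] = pre[x]
  post <- rbind(pre[rep(1, 7), ], pre[seq_len(nrow(pre) - 7), ])
  d7 <- dp_integer_displacement(pre, post, c(10, 1))
  interior <- d7$da[20:(nrow(pre) - 20), ]
  expect_true(all(interior == 7))
  expect_error(dp_integer_displacement(pre, post, c(0, 1)))
})

test_that("infinite continuity weight freezes the displacement path", {
  fx <- make_speckle_frame(2, ns = 300)
  set.seed(3)
  post <- fx$rf + matrix(stats::rnorm(length(fx$rf), sd = stats::sd(fx$rf)),
                         nrow(fx$rf))
  d <- dp_integer_displacement(fx$rf, post, c(4, 1),
                               regularization_weight = 1e6,
                               prev_weight = 1e6)
  expect_lte(length(unique(as.vector(d$da))), 1)
  expect_lte(length(unique(as.vector(d$dl))), 1)
})

test_that("optical-flow refinement recovers subsample shifts", {
  fx <- make_speckle_frame(4)
  # identical inputs: zero flow
  h0 <- hs_refine(fx$rf, fx$rf, n_iter = 50)
  expect_equal(max(abs(h0$axial)), 0, tolerance = 1e-10)
  # exact 0.3-sample shift rendered from displaced scatterers
  f2 <- fx$field
  f2$ax_mm <- f2$ax_mm + 0.3 * stpe:::axial_sample_mm(fx$spec)
  post <- synthesize_rf(f2, fx$spec, snr_db = Inf)
  h <- hs_refine(fx$rf, post, n_iter = 300, tol = 1e-8)
  wfc <- 2 * pi * fx$spec$fc / fx$spec$fs
  est <- mean(h$axial[50:350, 5:20]) * sin(wfc) / wfc
  expect_equal(est, 0.3, tolerance = 0.05)
  # infinite smoothness: spatially uniform flow
  hu <- hs_refine(fx$rf, post, smoothness_lambda = 1e8, n_iter = 50)
  expect_lt(diff(range(hu$axial)), 1e-4)
})

test_that("total displacement converts samples and lines to millimetres", {
  spec <- transducer_spec()
  int_f <- list(da = matrix(7L, 4, 3), dl = matrix(0L, 4, 3))
  sub_f <- list(axial = matrix(0.3, 4, 3), lateral = matrix(0.5, 4, 3))
  tot <- total_displacement(int_f, sub_f, spec)
  expect_equal(tot$axial_mm[1, 1], 7.3 * 1540 / 2 / 40e6 * 1000,
               tolerance = 1e-12)
  expect_equal(tot$lateral_mm[1, 1], 0.5 * spec$line_pitch_mm,
               tolerance = 1e-12)
  bad <- list(axial = matrix(0, 2, 2), lateral = matrix(0, 2, 2))
  expect_error(total_displacement(int_f, bad, spec))
})

test_that("least-squares strain is exact for polynomial displacement", {
  spec <- transducer_spec()
  dz <- stpe:::axial_sample_mm(spec)
  ns <- 300
  z <- (seq_len(ns) - 0.5) * dz
  # linear ramp of slope 0.01: strain exactly 0.01 away from the edges
  disp <- list(axial_mm = matrix(rep(0.01 * z, 5), ns, 5),
               lateral_mm = matrix(0, ns, 5))
  st <- strain_from_displacement(disp, spec, kernel_len = c(49, 3))
  expect_equal(st$axial[30:270, ], matrix(0.01, 241, 5), tolerance = 1e-10)
  # zero displacement gives zero strain
  zero <- list(axial_mm = matrix(0, ns, 5), lateral_mm = matrix(0, ns, 5))
  st0 <- strain_from_displacement(zero, spec, kernel_len = c(49, 3))
  expect_equal(max(abs(st0$axial)), 0)
  # quadratic displacement u = c z^2: slope 2 c z within the kernel bound
  cc <- 0.001
  disp2 <- list(axial_mm = matrix(rep(cc * z^2, 5), ns, 5),
                lateral_mm = matrix(0, ns, 5))
  st2 <- strain_from_displacement(disp2, spec, kernel_len = c(49, 3))
  mid <- 100:250
  expect_lt(max(abs(st2$axial[mid, 1] - 2 * cc * z[mid])), cc * 49 * dz)
  expect_error(strain_from_displacement(disp, spec, kernel_len = c(48, 3)))
  expect_error(strain_from_displacement(disp, spec, kernel_len = c(501, 3)))
})

test_that("the full tracking chain recovers a known strain movie", {
  # uniform 1% creep compression, noise-free RF
  lp <- 1 / (10 * aggregate_modulus(1e5, 0.3) * 2e4)
  mat <- material_params(1e5, 0.3, Lp = lp)
  spec <- phantom_spec(mat, mat, plane_lateral_mm = 15, plane_axial_mm = 15,
                       semi_axis_lateral_mm = 2, semi_axis_axial_mm = 2,
                       duration_s = 5, dt_s = 0.5, grid_mm = 0.5)
  ser <- generate_strain_series(spec)
  # a handful of frames is enough to exercise the accumulation chain
  keep <- 1:5
  ser$times <- ser$times[keep]
  ser$axial <- ser$axial[, , keep, drop = FALSE]
  ser$lateral <- ser$lateral[, , keep, drop = FALSE]
  tsp <- transducer_spec(n_lines = 48, aperture_mm = 15)
  rf <- simulate_rf_series(ser, tsp, snr_db = Inf, seed = 3)
  st <- track_rf_series(rf)
  d <- dim(st$axial)
  rs <- round(d[1] * 0.15):round(d[1] * 0.85)
  cs <- round(d[2] * 0.2):round(d[2] * 0.8)
  for (k in seq_len(d[3])) {
    tru_ax <- ser$axial[1, 1, k]
    tru_lat <- ser$lateral[1, 1, k]
    expect_lt(mean(abs(st$axial[rs, cs, k] - tru_ax)), 5e-4)
    expect_lt(mean(abs(st$lateral[rs, cs, k] - tru_lat)), 2e-3)
  }
  # determinism of the whole chain
  st2 <- track_rf_series(rf)
  expect_identical(st$axial, st2$axial)
})
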