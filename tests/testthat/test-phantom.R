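test_that("phantom spec validation enforces geometry and timing", {
  lp <- 1e-10
  bg <- material_params(3e4, 0.3, Lp = lp)
  inc <- material_params(6e4, 0.4, Lp = lp)
  expect_error(phantom_spec(inc, bg, semi_axis_lateral_mm = 15),
               "fit inside")
  expect_error(phantom_spec(inc, bg, duration_s = 0.5), "10 samples")
  expect_s3_class(small_phantom(), "phantom_spec")
})

test_that("inclusion mask area matches the analytic ellipse area", {
  spec <- small_phantom(grid_mm = 0.1, duration_s = 2, dt_s = 0.1)
  ser <- generate_strain_series(spec)
  # 7.5 mm diameter sphere on a 0.1 mm grid: pi * 37.5^2 pixels
  expect_equal(sum(ser$mask), pi * 37.5^2, tolerance = 0.02)
})

test_that("generated strain curves follow the first-order creep model", {
  ser <- generate_strain_series(small_phantom())
  tr <- ser$truth
  ij <- which(ser$mask, arr.ind = TRUE)[1, ]
  curve <- ser$axial[ij[1], ij[2], ]
  # identity at t = tau
  k <- which.min(abs(ser$times - tr$tau_in))
  expect_equal(curve[k], tr$eta_zz_in + (tr$alpha_zz_in - tr$eta_zz_in) / exp(1),
               tolerance = 1e-3)
  # steady state at the end of a 6-tau record
  expect_equal(curve[length(curve)], tr$eta_zz_in, tolerance = 0.003)
  # lateral curve shares the region time constant
  lat <- ser$lateral[ij[1], ij[2], ]
  expect_equal(lat[k], tr$eta_rr_in + (tr$alpha_rr_in - tr$eta_rr_in) / exp(1),
               tolerance = 1e-3)
})

test_that("contrast-1 phantoms are spatially uniform", {
  lp <- 1e-10
  bg <- material_params(3e4, 0.3, Lp = lp)
  spec <- phantom_spec(bg, bg, grid_mm = 0.5, duration_s = 10, dt_s = 0.5)
  ser <- generate_strain_series(spec)
  for (k in c(1, 10, 21)) {
    fr <- ser$axial[, , k]
    expect_lt(diff(range(fr)) / abs(mean(fr)), 1e-12)
  }
})

test_that("noise-free generation refit recovers the model parameters", {
  ser <- generate_strain_series(small_phantom())
  ij <- which(ser$mask, arr.ind = TRUE)[5, ]
  f <- varpro_fit(ser$times, ser$axial[ij[1], ij[2], ])
  tr <- ser$truth
  expect_equal(f$alpha, tr$alpha_zz_in, tolerance = 1e-3)
  expect_equal(f$eta, tr$eta_zz_in, tolerance = 1e-3)
  expect_equal(f$tau, tr$tau_in, tolerance = 1e-3)
})

test_that("strain noise injection hits the requested SNR and is reproducible", {
  ser <- generate_strain_series(small_phantom(grid_mm = 1))
  noisy <- add_strain_noise(ser, 40, seed = 3)
  snr_emp <- 20 * log10(sqrt(mean(ser$axial^2)) /
                          sqrt(mean((noisy$axial - ser$axial)^2)))
  expect_lt(abs(snr_emp - 40), 0.5)
  noisy2 <- add_strain_noise(ser, 40, seed = 3)
  expect_identical(noisy$axial, noisy2$axial)
  expect_identical(add_strain_noise(ser, Inf, seed = 1)$axial, ser$axial)
})
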