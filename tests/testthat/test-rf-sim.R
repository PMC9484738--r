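test_that("scatterer fields have the requested density and are reproducible", {
  spec <- transducer_spec()
  f <- make_scatterer_field(c(20, 40), 10, seed = 1, spec = spec)
  sigma_t <- sqrt(2 * log(2)) / (pi * spec$fbw * spec$fc)
  cell <- spec$beamwidth_mm * (2.355 * sigma_t * spec$c_m_s / 2 * 1000)
  expect_equal(nrow(f), 10 * 20 * 40 / cell, tolerance = 0.05)
  f2 <- make_scatterer_field(c(20, 40), 10, seed = 1, spec = spec)
  expect_identical(f$lat_mm, f2$lat_mm)
  expect_error(make_scatterer_field(c(0, 40), 10, seed = 1))
  expect_error(make_scatterer_field(c(20, 40), 0.5, seed = 1))
})

test_that("the point spread function matches its frequency-domain spec", {
  spec <- transducer_spec()
  psf <- make_psf(spec)
  ax <- attr(psf, "axial")
  # peak at the center sample
  expect_equal(which.max(abs(psf)), which(abs(psf) == 1)[1])
  expect_equal(which.max(ax), (length(ax) + 1) / 2)
  # spectral peak at fc within one FFT bin, -6 dB width within 5% of fbw*fc
  n <- 2^14
  A <- abs(stats::fft(c(ax, rep(0, n - length(ax)))))[1:(n / 2)]
  fr <- (0:(n / 2 - 1)) * spec$fs / n
  expect_lt(abs(fr[which.max(A)] - spec$fc), spec$fs / n * 1.5)
  above <- fr[A >= max(A) / 2]
  expect_equal(max(above) - min(above), spec$fbw * spec$fc, tolerance = 0.05)
  expect_error(transducer_spec(fs = 10e6))
})

test_that("scatterer displacement interpolates the maps bilinearly", {
  spec <- transducer_spec(n_lines = 32, aperture_mm = 10)
  f <- make_scatterer_field(c(10, 10), 4, seed = 2, spec = spec)
  zero <- matrix(0, 20, 20)
  same <- displace_scatterers(f, zero, zero, c(0.5, 0.5))
  expect_equal(same$ax_mm, f$ax_mm)
  shifted <- displace_scatterers(f, zero + 0.1, zero, c(0.5, 0.5))
  expect_equal(shifted$ax_mm, f$ax_mm + 0.1, tolerance = 1e-12)
  # linear axial ramp (1% compression toward the surface): pairwise gaps
  # shrink by 1%
  zmap <- matrix(rep(-0.01 * (seq_len(20) - 0.5) * 0.5, 20), 20, 20)
  comp <- displace_scatterers(f, zmap, zero, c(0.5, 0.5))
  # interior scatterers only: outside the map node range the displacement
  # is clamped to the edge value by contract
  ord <- order(f$ax_mm)
  interior <- f$ax_mm[ord] > 0.5 & f$ax_mm[ord] < 9.5
  gaps0 <- diff(f$ax_mm[ord][interior])
  gaps1 <- diff(comp$ax_mm[ord][interior])
  keep <- gaps0 > 1e-4
  expect_equal(gaps1[keep] / gaps0[keep], rep(0.99, sum(keep)),
               tolerance = 1e-6)
})

test_that("synthesized RF hits the requested SNR and is deterministic", {
  spec <- transducer_spec(n_lines = 32, aperture_mm = 10)
  f <- make_scatterer_field(c(10, 10), 10, seed = 3, spec = spec)
  clean <- synthesize_rf(f, spec, snr_db = Inf)
  noisy <- synthesize_rf(f, spec, snr_db = 40, seed = 4)
  snr_emp <- 20 * log10(sqrt(mean(clean^2)) / sqrt(mean((noisy - clean)^2)))
  expect_lt(abs(snr_emp - 40), 0.5)
  expect_identical(synthesize_rf(f, spec, snr_db = 40, seed = 4), noisy)
  # empty field: pure noise at the configured floor
  empty <- f[0, , drop = FALSE]
  attr(empty, "extent_mm") <- attr(f, "extent_mm")
  class(empty) <- class(f)
  pure <- synthesize_rf(empty, spec, snr_db = 20, seed = 5,
                        noise_floor_rms = 2)
  expect_equal(sqrt(mean(pure^2)), 2, tolerance = 0.05)
})

test_that("homogeneous speckle has a Rayleigh-like envelope", {
  spec <- transducer_spec(n_lines = 48, aperture_mm = 15)
  f <- make_scatterer_field(c(15, 15), 10, seed = 6, spec = spec)
  rf <- synthesize_rf(f, spec, snr_db = Inf)
  central <- rf[100:680, 8:41]
  # envelope via magnitude of the analytic signal, column-wise
  env <- abs(apply(central, 2, function(x) {
    n <- length(x)
    X <- stats::fft(x)
    h <- c(1, rep(2, floor((n - 1) / 2)), rep(1, 1 - n %% 2),
           rep(0, ceiling((n - 1) / 2)))
    stats::fft(X * h, inverse = TRUE) / n
  }))
  env <- as.vector(env) / sqrt(mean(env^2) / 2)
  ks <- suppressWarnings(stats::ks.test(env, function(q) 1 - exp(-q^2 / 2)))
  expect_lt(unname(ks$statistic), 0.05)
})

test_that("rf series generation records geometry and timing", {
  spec <- small_phantom(grid_mm = 1, duration_s = 5, dt_s = 0.5)
  ser <- generate_strain_series(spec)
  tsp <- transducer_spec(n_lines = 24, aperture_mm = 20)
  rf <- simulate_rf_series(ser, tsp, snr_db = Inf, seed = 1)
  expect_s3_class(rf, "rf_series")
  expect_equal(dim(rf$frames)[3], length(ser$times) + 1)
  expect_equal(rf$times, ser$times)
  expect_identical(rf$source_geometry, ser$geometry)
})
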