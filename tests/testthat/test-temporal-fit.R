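test_that("the creep bound coefficients are the exponential remainders", {
  expect_equal(round(strain_bound_coefficient(2), 3), 0.135)
  expect_equal(round(strain_bound_coefficient(1), 3), 0.368)
  expect_equal(strain_bound_coefficient(0), 1)
  expect_error(strain_bound_coefficient(-1))
})

test_that("EOF denoising reconstructs, denoises and is idempotent", {
  set.seed(2)
  spec <- small_phantom(grid_mm = 1, duration_s = 20, dt_s = 0.5)
  ser <- generate_strain_series(spec)
  noisy <- add_strain_noise(ser, 30, seed = 9)

  d <- dim(ser$axial)
  full_rank <- min(d[1] * d[2], d[3])
  ident <- eof_denoise(noisy, full_rank)
  expect_equal(ident$axial, noisy$axial, tolerance = 1e-8)

  # phantom stacks are low rank: truncation must beat the raw noise
  den <- eof_denoise(noisy, 3)
  expect_lt(mean((den$axial - ser$axial)^2), mean((noisy$axial - ser$axial)^2))

  twice <- eof_denoise(den, 3)
  expect_equal(twice$axial, den$axial, tolerance = 1e-9)
  expect_error(eof_denoise(noisy, full_rank + 1), "rank")
  en <- attr(den, "eof_energy")
  expect_true(all(en > 0.9 & en <= 1))
})

test_that("variable projection recovers exact exponentials and flags degeneracy", {
  t <- seq(0, 60, 0.1)
  s <- 0.03 + (0.02 - 0.03) * exp(-t / 10)
  f <- varpro_fit(t, s)
  expect_equal(f$alpha, 0.02, tolerance = 1e-6)
  expect_equal(f$eta, 0.03, tolerance = 1e-6)
  expect_equal(f$tau, 10, tolerance = 1e-6)
  expect_false(f$degenerate)

  g <- varpro_fit(t, rep(0.05, length(t)))
  expect_true(g$degenerate)
  expect_equal(g$eta, 0.05)
  expect_true(is.nan(g$tau))
  expect_error(varpro_fit(t[1:3], s[1:3]))
})

test_that("variable projection agrees with an exhaustive grid-search oracle", {
  set.seed(7)
  t <- seq(0, 30, 0.25)
  grid_oracle <- function(y) {
    taus <- exp(seq(log(0.05), log(300), length.out = 1e4))
    rss <- vapply(taus, function(tau) {
      B <- cbind(1, exp(-t / tau))
      r <- y - B %*% qr.solve(B, y)
      sum(r^2)
    }, 0)
    list(tau = taus[which.min(rss)], rss = min(rss))
  }
  for (i in 1:30) {
    tau <- stats::runif(1, 1, 20)
    y <- 0.03 - 0.01 * exp(-t / tau) + stats::rnorm(length(t), sd = 5e-4)
    f <- varpro_fit(t, y)
    o <- grid_oracle(y)
    # within one cell of the fine oracle grid and never a worse residual
    expect_equal(log(f$tau), log(o$tau), tolerance = log(300 / 0.05) / 1e4 * 3)
    expect_lte(f$rss, o$rss * (1 + 1e-8))
  }
})

test_that("field fitting recovers the steady-state maps over windows", {
  ser <- generate_strain_series(small_phantom())
  tr <- ser$truth
  pm_full <- fit_field(ser)
  expect_equal(mean(pm_full$eta[ser$mask]), tr$eta_zz_in, tolerance = 1e-3)
  expect_equal(mean(pm_full$eta_lateral[ser$mask]), tr$eta_rr_in,
               tolerance = 1e-3)
  # model-exact data: the 2-tau window gives the same steady state
  pm_2tc <- fit_field(ser, window_len_s = 2 * tr$tau_in)
  expect_equal(pm_2tc$eta[ser$mask], pm_full$eta[ser$mask], tolerance = 1e-4)
  # background axial has no transient: degenerate, eta = constant level
  expect_true(all(pm_full$degenerate[!ser$mask & !is.na(pm_full$eta)] |
                    is.na(pm_full$tau[!ser$mask])))
  expect_error(fit_field(ser, window_len_s = 0.05))
})

test_that("time-constant error grows as the window shrinks on noisy data", {
  spec <- small_phantom(grid_mm = 1)
  ser <- add_strain_noise(generate_strain_series(spec), 40, seed = 5)
  tau <- ser$truth$tau_in
  med_err <- sapply(c(2, 1, 0.5) * tau, function(w) {
    pm <- fit_field(ser, window_len_s = w, mask = ser$mask)
    stats::median(abs(pm$tau[ser$mask] - tau) / tau, na.rm = TRUE)
  })
  expect_lte(med_err[1], med_err[2])
  expect_lte(med_err[2], med_err[3])
})

test_that("time-constant outliers are replaced by the in-mask median", {
  tau <- matrix(c(10, 11, 12, 150), 2, 2)
  mask <- matrix(TRUE, 2, 2)
  fixed <- replace_tc_outliers(tau, mask)
  expect_equal(fixed[2, 2], 11)
  expect_equal(fixed[1:3], tau[1:3])
  # NaN (degenerate) entries are treated as outliers
  tau[1, 1] <- NaN
  expect_equal(replace_tc_outliers(tau, mask)[1, 1], 11.5)
  expect_error(replace_tc_outliers(matrix(c(200, NaN), 1, 2),
                                   matrix(TRUE, 1, 2)), "outliers")
  expect_message(replace_tc_outliers(matrix(10, 2, 2), matrix(TRUE, 2, 2),
                                     threshold_s = 50), "default")
})

test_that("masked median filtering pools only in-mask neighbours", {
  M <- matrix(1, 5, 5)
  M[3, 3] <- 100
  mask <- matrix(TRUE, 5, 5)
  mask[, 5] <- FALSE
  M[, 5] <- 1e6
  out <- masked_median_filter(M, mask, half = 1)
  expect_equal(out[3, 3], 1)
  expect_equal(out[, 5], rep(1e6, 5))   # outside mask untouched
})
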