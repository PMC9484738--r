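test_that("background moduli follow the uniaxial definitions", {
  bm <- background_moduli(1000, 0.1, 0)
  expect_equal(bm$E_b, 1e4)
  expect_equal(bm$nu_b, 0)
  expect_error(background_moduli(1000, 0, 0.1))
  # round trip through the forward phantom
  ser <- generate_strain_series(small_phantom())
  tr <- ser$truth
  bm <- background_moduli(1000, tr$eta_zz_bg, tr$eta_rr_bg)
  expect_equal(bm$E_b, 3e4, tolerance = 0.005)
  expect_equal(bm$nu_b, 0.3, tolerance = 0.005)
})

test_that("inclusion inversion round-trips the forward model", {
  bg <- material_params(1e4, 0.3)
  inc <- material_params(2e4, 0.4)
  f <- eshelby_forward_strain(bg, inc, "sphere", 1000)
  est <- invert_inclusion(c(f$eps_zz_in, f$eps_rr_in),
                          c(f$eps_zz_bg, f$eps_rr_bg), 1e4, 0.3, "sphere")
  expect_equal(est$E_i, 2e4, tolerance = 1e-4)
  expect_equal(est$nu_i, 0.4, tolerance = 1e-4)
  expect_gte(est$cost, 0)
  expect_lt(est$cost, 1e-15)
  # no contrast: recovers the background moduli
  f0 <- eshelby_forward_strain(bg, bg, "sphere", 1000)
  est0 <- invert_inclusion(c(f0$eps_zz_in, f0$eps_rr_in),
                           c(f0$eps_zz_bg, f0$eps_rr_bg), 1e4, 0.3, "sphere")
  expect_equal(est0$E_i, 1e4, tolerance = 1e-3)
  expect_equal(est0$nu_i, 0.3, tolerance = 1e-3)
})

test_that("noise-free recovery holds over a grid of contrasts and ratios", {
  bg <- material_params(1e4, 0.3)
  for (ct in c(0.5, 1, 2, 3, 4)) {
    for (nu in c(0.1, 0.2, 0.3, 0.4, 0.45)) {
      inc <- material_params(ct * 1e4, nu)
      f <- eshelby_forward_strain(bg, inc, "sphere", 1000)
      est <- suppressWarnings(
        invert_inclusion(c(f$eps_zz_in, f$eps_rr_in),
                         c(f$eps_zz_bg, f$eps_rr_bg), 1e4, 0.3, "sphere"))
      expect_equal(est$E_i / 1e4, ct, tolerance = 1e-3)
      expect_equal(est$nu_i, nu, tolerance = 1e-3)
    }
  }
})

test_that("ROI-averaged inversion tolerates measurement noise", {
  set.seed(12)
  bg <- material_params(1e4, 0.3)
  inc <- material_params(2e4, 0.4)
  f <- eshelby_forward_strain(bg, inc, "sphere", 1000)
  # 40 dB noise on strain components, averaged over a 200-pixel ROI
  n <- 200
  noisy <- function(x) mean(x * (1 + stats::rnorm(n, sd = 0.01)))
  est <- invert_inclusion(c(noisy(f$eps_zz_in), noisy(f$eps_rr_in)),
                          c(noisy(f$eps_zz_bg), noisy(f$eps_rr_bg)),
                          1e4, 0.3, "sphere")
  expect_equal(est$E_i, 2e4, tolerance = 0.05)
  expect_equal(est$nu_i, 0.4, tolerance = 0.05)
})

test_that("spheroid inversion round-trips with its own tensor", {
  bg <- material_params(1e4, 0.35)
  inc <- material_params(3e4, 0.25)
  f <- eshelby_forward_strain(bg, inc, "spheroid", 1000, aspect = 5 / 7.5)
  est <- invert_inclusion(c(f$eps_zz_in, f$eps_rr_in),
                          c(f$eps_zz_bg, f$eps_rr_bg), 1e4, 0.35,
                          shape = 5 / 7.5)
  expect_equal(est$E_i, 3e4, tolerance = 1e-3)
  expect_equal(est$nu_i, 0.25, tolerance = 1e-3)
})

test_that("best-fit ellipse recovers circular and elliptical masks", {
  grid <- 0.1
  xy <- expand.grid(ax = seq(grid / 2, 20, grid), lat = seq(grid / 2, 20, grid))
  circ <- matrix((xy$ax - 10)^2 + (xy$lat - 10)^2 <= 3.75^2,
                 nrow = length(seq(grid / 2, 20, grid)))
  fe <- fit_ellipsoid(circ, c(grid, grid))
  expect_equal(fe$l1_mm, 3.75, tolerance = 0.02)
  expect_equal(fe$l2_mm, 3.75, tolerance = 0.02)

  ell <- matrix(((xy$ax - 10) / 2.5)^2 + ((xy$lat - 10) / 3.75)^2 <= 1,
                nrow = length(seq(grid / 2, 20, grid)))
  fe2 <- fit_ellipsoid(ell, c(grid, grid))
  expect_equal(fe2$l1_mm, 2.5, tolerance = 0.03)
  expect_equal(fe2$l2_mm, 3.75, tolerance = 0.03)
  expect_equal(fe2$aspect_axial_lateral, 2.5 / 3.75, tolerance = 0.03)
  # major axis along the lateral direction: orientation ~ 0 mod pi
  expect_lt(min(fe2$orientation %% pi, pi - fe2$orientation %% pi), 2 * pi / 180)

  # rotated ellipse: orientation recovered mod pi within 2 degrees
  th <- 30 * pi / 180
  u <- cos(th) * (xy$lat - 10) + sin(th) * (xy$ax - 10)
  v <- -sin(th) * (xy$lat - 10) + cos(th) * (xy$ax - 10)
  rot <- matrix((u / 3.75)^2 + (v / 2)^2 <= 1, nrow = nrow(ell))
  fe3 <- fit_ellipsoid(rot, c(grid, grid))
  expect_lt(abs(fe3$orientation - th) %% pi, 2 * pi / 180)
  expect_error(fit_ellipsoid(matrix(FALSE, 5, 5)))
})
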