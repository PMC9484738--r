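# Quadrature oracle for the spheroid I-integrals (transverse semi-axis 1,
# axial semi-axis t), straight from their defining improper integrals.
quad_I <- function(ai2, t) {
  2 * pi * t * stats::integrate(function(s)
    1 / ((ai2 + s) * sqrt((1 + s)^2 * (t^2 + s))),
    0, Inf, rel.tol = 1e-12)$value
}
quad_Iij <- function(ai2, aj2, t) {
  2 * pi * t * stats::integrate(function(s)
    1 / ((ai2 + s) * (aj2 + s) * sqrt((1 + s)^2 * (t^2 + s))),
    0, Inf, rel.tol = 1e-12)$value
}

# Independent brute-force equivalent-inclusion solve in full 6x6 Voigt
# notation (engineering shear), used as the oracle for the forward solution.
voigt_stiffness <- function(E, nu) {
  la <- E * nu / ((1 + nu) * (1 - 2 * nu))
  mu <- E / (2 * (1 + nu))
  C <- diag(c(rep(2 * mu, 3), rep(mu, 3)))
  C[1:3, 1:3] <- C[1:3, 1:3] + la
  C
}
voigt_eshelby <- function(S) {
  cm <- S$components
  M <- matrix(0, 6, 6)
  M[1:3, 1:3] <- matrix(c(cm$S1111, cm$S1122, cm$S1133,
                          cm$S2211, cm$S2222, cm$S2233,
                          cm$S3311, cm$S3322, cm$S3333), 3, 3, byrow = TRUE)
  M[4, 4] <- 2 * cm$S2323
  M[5, 5] <- 2 * cm$S1313
  M[6, 6] <- 2 * cm$S1212
  M
}
oracle_forward <- function(bg, inc, S, sigma0) {
  Cb <- voigt_stiffness(bg$E, bg$nu)
  Ci <- voigt_stiffness(inc$E, inc$nu)
  Sv <- voigt_eshelby(S)
  eps0 <- c(bg$nu * sigma0 / bg$E, bg$nu * sigma0 / bg$E, -sigma0 / bg$E,
            0, 0, 0)
  A <- (Ci - Cb) %*% Sv + Cb
  est <- solve(A, (Cb - Ci) %*% eps0)
  drop(eps0 + Sv %*% est)
}

test_that("sphere tensor matches its closed forms and symmetries", {
  S <- eshelby_tensor_sphere(0.3)
  expect_equal(S$components$S1111, (7 - 5 * 0.3) / (15 * 0.7))
  expect_equal(S$components$S1122, S$components$S2211)
  # nu -> 0.5 limit of S_1111 is (7 - 2.5)/(15 * 0.5) = 0.6
  expect_equal(eshelby_tensor_sphere(0.4999)$components$S1111, 0.6,
               tolerance = 1e-3)
  # dilatational eigenstrain maps to the volumetric factor (1+nu)/(3(1-nu))
  Sn <- stpe:::normal_block(S)
  expect_equal(drop(Sn %*% c(1, 1, 1)), rep((1 + 0.3) / (3 * 0.7), 3),
               tolerance = 1e-12)
  expect_error(eshelby_tensor_sphere(0.6))
})

test_that("spheroid tensor components reproduce the quadrature I-integrals", {
  for (t in c(5 / 7.5, 0.4, 1.8, 3)) {
    I <- stpe:::spheroid_I_integrals(t)
    expect_equal(I$I1, quad_I(1, t), tolerance = 1e-8)
    expect_equal(I$I3, quad_I(t^2, t), tolerance = 1e-8)
    expect_equal(I$I11, quad_Iij(1, 1, t), tolerance = 1e-8)
    expect_equal(I$I13, quad_Iij(1, t^2, t), tolerance = 1e-8)
    expect_equal(I$I33, quad_Iij(t^2, t^2, t), tolerance = 1e-8)
  }
  # the standard elliptical-inclusion geometry: axial 5 mm over lateral 7.5 mm
  S <- eshelby_tensor_spheroid(0.3, 5 / 7.5)
  expect_true(all(is.finite(unlist(S$components))))
  # volumetric identity holds for the spheroid too
  Sn <- stpe:::normal_block(S)
  expect_equal(sum(Sn %*% c(1, 1, 1)) / 3, (1 + 0.3) / (3 * 0.7),
               tolerance = 1e-10)
})

test_that("spheroid tensor is continuous at the sphere", {
  S0 <- eshelby_tensor_sphere(0.35)
  for (a in c(1 - 1e-6, 1 + 1e-6)) {
    S1 <- eshelby_tensor_spheroid(0.35, a)
    expect_equal(unlist(S1$components), unlist(S0$components),
                 tolerance = 1e-4)
  }
  expect_error(eshelby_tensor_spheroid(0.3, -1))
})

test_that("forward interior strain matches the 6x6 Voigt oracle", {
  bg <- material_params(1e4, 0.3)
  inc <- material_params(2e4, 0.4)
  f <- eshelby_forward_strain(bg, inc, "sphere", 1000)
  or <- oracle_forward(bg, inc, eshelby_tensor_sphere(0.3), 1000)
  expect_equal(f$eps_zz_in, -or[3], tolerance = 1e-10)
  expect_equal(f$eps_rr_in, or[1], tolerance = 1e-10)

  set.seed(42)
  for (i in 1:20) {
    bg <- material_params(10^stats::runif(1, 3.5, 4.5), stats::runif(1, 0.05, 0.45))
    inc <- material_params(10^stats::runif(1, 3.5, 5), stats::runif(1, 0.05, 0.45))
    aspect <- stats::runif(1, 0.4, 2.5)
    S <- eshelby_tensor_spheroid(bg$nu, aspect)
    f <- eshelby_forward_strain(bg, inc, S, 1000)
    or <- oracle_forward(bg, inc, S, 1000)
    expect_equal(f$eps_zz_in, -or[3], tolerance = 1e-10)
    expect_equal(f$eps_rr_in, or[1], tolerance = 1e-10)
  }
})

test_that("forward strain limiting cases behave physically", {
  bg <- material_params(1e4, 0.3)
  # homogeneous: interior equals far field exactly
  f <- eshelby_forward_strain(bg, material_params(1e4, 0.3), "sphere", 1000)
  expect_equal(f$eps_zz_in, f$eps_zz_bg, tolerance = 1e-14)
  expect_equal(f$eps_rr_in, f$eps_rr_bg, tolerance = 1e-14)
  # stiffer inclusion strains less
  f2 <- eshelby_forward_strain(bg, material_params(2e4, 0.3), "sphere", 1000)
  expect_lt(abs(f2$eps_zz_in), abs(f2$eps_zz_bg))
  expect_error(eshelby_forward_strain(bg, bg, "sphere", -5))
})
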