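# Eshelby tensors for spherical and spheroidal inclusions, and the
# equivalent-inclusion forward solution for an ellipsoidal inhomogeneity
# under remote uniaxial stress. Axis 3 is the axial (compression) direction
# and the symmetry axis of the spheroid; axes 1 and 2 are transverse.

new_eshelby_tensor <- function(components, nu_b, aspect) {
  structure(list(components = components, nu_b = nu_b, aspect = aspect),
            class = "eshelby_tensor")
}

#' @export
print.eshelby_tensor <- function(x, ...) {
  cat(sprintf("Eshelby tensor: aspect = %.4g, background nu = %.4g\n",
              x$aspect, x$nu_b))
  print(unlist(x$components))
  invisible(x)
}

#' Eshelby tensor of a spherical inclusion
#'
#' Classical closed forms for an isotropic matrix:
#' `S_1111 = (7 - 5 nu) / (15 (1 - nu))`,
#' `S_1122 = (5 nu - 1) / (15 (1 - nu))`,
#' `S_1212 = (4 - 5 nu) / (15 (1 - nu))`, with all index symmetries.
#'
#' @param nu_b Poisson's ratio of the background (matrix), in `[0, 0.5)`.
#' @return An `eshelby_tensor` object; `$components` holds the distinct
#'   entries, `normal_block()` extracts the 3x3 matrix acting on normal
#'   strain components.
#' @export
eshelby_tensor_sphere <- function(nu_b) {
  if (!is.finite(nu_b) || nu_b < 0 || nu_b >= 0.5)
    stop("background Poisson's ratio must lie in [0, 0.5)")
  d <- 15 * (1 - nu_b)
  Sd <- (7 - 5 * nu_b) / d   # S_iiii
  So <- (5 * nu_b - 1) / d   # S_iijj, i != j
  Ss <- (4 - 5 * nu_b) / d   # S_ijij, i != j
  comps <- list(S1111 = Sd, S2222 = Sd, S3333 = Sd,
                S1122 = So, S2211 = So, S1133 = So, S3311 = So,
                S2233 = So, S3322 = So,
                S1212 = Ss, S1313 = Ss, S2323 = Ss)
  new_eshelby_tensor(comps, nu_b, aspect = 1)
}

# Closed-form I-integrals of a spheroid with transverse semi-axis 1 and
# axial semi-axis `aspect` (Routh/ellipsoid potentials). I1 + I2 + I3 = 4 pi.
spheroid_I_integrals <- function(aspect) {
  if (aspect > 1) {            # prolate, axial axis longer
    e <- sqrt(aspect^2 - 1)
    I1 <- 2 * pi * aspect / e^3 * (aspect * e - acosh(aspect))
  } else {                     # oblate
    e <- sqrt(1 - aspect^2)
    I1 <- 2 * pi * aspect / e^3 * (acos(aspect) - aspect * e)
  }
  I3 <- 4 * pi - 2 * I1
  I13 <- (I1 - I3) / (aspect^2 - 1)
  I11 <- pi - I13 / 4                    # = I12 (a1 = a2 = 1)
  I33 <- (4 * pi / aspect^2 - 2 * I13) / 3
  list(I1 = I1, I3 = I3, I11 = I11, I12 = I11, I13 = I13, I33 = I33)
}

#' Eshelby tensor of a spheroidal inclusion
#'
#' Axisymmetric spheroid with transverse semi-axes `a1 = a2` and axial
#' semi-axis `a3 = aspect * a1`; components are assembled from the
#' closed-form elliptic I-integrals, with oblate (`aspect < 1`) and prolate
#' (`aspect > 1`) branches. `aspect` within `1e-5` of 1 delegates to
#' [eshelby_tensor_sphere()].
#'
#' @param nu_b Background Poisson's ratio, in `[0, 0.5)`.
#' @param aspect Axial over transverse semi-axis ratio, positive.
#' @return An `eshelby_tensor` object.
#' @export
eshelby_tensor_spheroid <- function(nu_b, aspect) {
  if (!is.finite(aspect) || aspect <= 0) stop("aspect ratio must be positive")
  if (!is.finite(nu_b) || nu_b < 0 || nu_b >= 0.5)
    stop("background Poisson's ratio must lie in [0, 0.5)")
  if (abs(aspect - 1) < 1e-5) {
    out <- eshelby_tensor_sphere(nu_b)
    out$aspect <- aspect
    return(out)
  }
  I <- spheroid_I_integrals(aspect)
  a1sq <- 1
  a3sq <- aspect^2
  c1 <- 1 / (8 * pi * (1 - nu_b))
  c2 <- (1 - 2 * nu_b) * c1
  S1111 <- 3 * c1 * a1sq * I$I11 + c2 * I$I1
  S3333 <- 3 * c1 * a3sq * I$I33 + c2 * I$I3
  S1122 <- c1 * a1sq * I$I12 - c2 * I$I1
  S1133 <- c1 * a3sq * I$I13 - c2 * I$I1
  S3311 <- c1 * a1sq * I$I13 - c2 * I$I3
  S1212 <- c1 * a1sq * I$I12 + c2 * I$I1
  S1313 <- c1 * (a1sq + a3sq) / 2 * I$I13 + c2 * (I$I1 + I$I3) / 2
  comps <- list(S1111 = S1111, S2222 = S1111, S3333 = S3333,
                S1122 = S1122, S2211 = S1122,
                S1133 = S1133, S3311 = S3311,
                S2233 = S1133, S3322 = S3311,
                S1212 = S1212, S1313 = S1313, S2323 = S1313)
  new_eshelby_tensor(comps, nu_b, aspect)
}

# 3x3 block of the Eshelby tensor mapping diagonal (normal) eigenstrains to
# diagonal constrained strains; sufficient for the axisymmetric shear-free
# problem treated here.
normal_block <- function(S) {
  cm <- S$components
  matrix(c(cm$S1111, cm$S1122, cm$S1133,
           cm$S2211, cm$S2222, cm$S2233,
           cm$S3311, cm$S3322, cm$S3333),
         nrow = 3, byrow = TRUE)
}

# Isotropic stiffness acting on normal strain components.
stiffness_normal <- function(E, nu) {
  la <- E * nu / ((1 + nu) * (1 - 2 * nu))
  mu <- E / (2 * (1 + nu))
  matrix(c(la + 2 * mu, la, la,
           la, la + 2 * mu, la,
           la, la, la + 2 * mu), nrow = 3, byrow = TRUE)
}

resolve_tensor <- function(shape, nu_b, aspect = 1) {
  if (inherits(shape, "eshelby_tensor")) return(shape)
  if (is.numeric(shape)) return(eshelby_tensor_spheroid(nu_b, shape))
  shape <- match.arg(shape, c("sphere", "spheroid"))
  if (shape == "sphere") eshelby_tensor_sphere(nu_b)
  else eshelby_tensor_spheroid(nu_b, aspect)
}

#' Interior and far-field strains of an ellipsoidal inhomogeneity
#'
#' Equivalent-inclusion solution for an isotropic ellipsoidal inhomogeneity
#' embedded in an isotropic background under remote uniaxial compression of
#' magnitude `sigma0` along the axial (symmetry) axis. The interior strain
#' is spatially uniform: `eps_in = eps0 + S eps*`, with the eigenstrain
#' `eps*` solved from `[(C_i - C_b) S + C_b] eps* = (C_b - C_i) eps0`.
#'
#' Reported strains follow the imaging convention: axial strains are
#' positive in compression, lateral strains positive in expansion.
#'
#' @param bg,inc [material_params()] of background and inclusion.
#' @param shape `"sphere"`, `"spheroid"`, a numeric aspect ratio
#'   (axial/lateral), or a prebuilt `eshelby_tensor`.
#' @param sigma0 Magnitude of the applied compressive axial stress, Pa.
#' @param aspect Aspect ratio when `shape = "spheroid"`.
#' @return List with `eps_zz_in`, `eps_rr_in` (uniform interior axial and
#'   lateral strain), `eps_zz_bg`, `eps_rr_bg` (far-field values), and the
#'   solved eigenstrain vector `eigenstrain` (signed, normal components).
#' @examples
#' bg <- material_params(1e4, 0.3)
#' inc <- material_params(2e4, 0.4)
#' eshelby_forward_strain(bg, inc, "sphere", sigma0 = 1000)
#' @export
eshelby_forward_strain <- function(bg, inc, shape = "sphere", sigma0, aspect = 1) {
  stopifnot(inherits(bg, "material_params"), inherits(inc, "material_params"))
  if (!is.finite(sigma0) || sigma0 <= 0) stop("sigma0 must be a positive stress magnitude")
  S <- resolve_tensor(shape, bg$nu, aspect)
  Sn <- normal_block(S)
  Cb <- stiffness_normal(bg$E, bg$nu)
  Ci <- stiffness_normal(inc$E, inc$nu)
  # signed remote strain for stress -sigma0 along axis 3
  eps0 <- c(bg$nu * sigma0 / bg$E, bg$nu * sigma0 / bg$E, -sigma0 / bg$E)
  A <- (Ci - Cb) %*% Sn + Cb
  est <- tryCatch(solve(A, (Cb - Ci) %*% eps0),
                  error = function(e) stop("singular equivalent-inclusion system: ",
                                           conditionMessage(e)))
  eps_in <- eps0 + Sn %*% est
  list(eps_zz_in = -eps_in[3], eps_rr_in = eps_in[1],
       eps_zz_bg = sigma0 / bg$E, eps_rr_bg = bg$nu * sigma0 / bg$E,
       eigenstrain = drop(est))
}
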