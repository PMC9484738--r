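# Inversion of elastic moduli from steady-state strains: background moduli
# from the far field, inclusion Young's modulus and Poisson's ratio by
# Eshelby cost-function minimisation, and the best-fit ellipsoid of an
# irregular mask.

#' Background moduli from far-field steady-state strains
#'
#' Under remote uniaxial compression `E_b = sigma0 / |eps_zz|` and
#' `nu_b = |eps_rr| / |eps_zz|` (clamped to `[0, 0.499]`). Strains are the
#' steady-state background values averaged over a region far from the
#' inclusion, in the imaging convention (axial compression-positive,
#' lateral expansion-positive).
#'
#' @param sigma0 Applied axial stress magnitude, Pa.
#' @param eps_zz_b,eps_rr_b Background axial and lateral steady-state
#'   strains.
#' @return List with `E_b` (Pa) and `nu_b`.
#' @export
background_moduli <- function(sigma0, eps_zz_b, eps_rr_b) {
  if (!is.finite(eps_zz_b) || eps_zz_b == 0) stop("background axial strain must be non-zero")
  E_b <- sigma0 / abs(eps_zz_b)
  nu_b <- min(max(abs(eps_rr_b) / abs(eps_zz_b), 0), 0.499)
  list(E_b = E_b, nu_b = nu_b)
}

# Eigenstrain from measured strains and geometry only: eps* = S^-1 (eps_in - eps0).
eigenstrain_geometric <- function(Sn, eps_in_signed, eps0_signed) {
  solve(Sn, eps_in_signed - eps0_signed)
}

# Eigenstrain from the equivalency condition given candidate inclusion moduli.
eigenstrain_material <- function(Sn, Cb, E_i, nu_i, eps0_signed) {
  Ci <- stiffness_normal(E_i, nu_i)
  solve((Ci - Cb) %*% Sn + Cb, (Cb - Ci) %*% eps0_signed)
}

#' Invert inclusion Young's modulus and Poisson's ratio
#'
#' The cost is the squared difference between two expressions of the
#' eigenstrain inside the inclusion: one obtained purely geometrically from
#' the measured strains (`S^-1 (eps_in - eps0)`), the other from the
#' equivalent-inclusion equivalency at candidate `(E_i, nu_i)`. Both use
#' only the axial and lateral strain components available from imaging (the
#' unobserved elevational component is set equal to the lateral one by
#' axisymmetry). The minimum is found by multi-start bounded local
#' optimisation over `E_i in [0.05, 50] E_b`, `nu_i in [0.01, 0.499]`,
#' seeded from a closed-form linear estimate.
#'
#' @param eps_in Inclusion steady-state strains `c(zz, rr)` in the imaging
#'   convention (axial compression-positive, lateral expansion-positive).
#' @param eps_bg Background (far-field) steady-state strains `c(zz, rr)`,
#'   same convention.
#' @param E_b,nu_b Background moduli (e.g. from [background_moduli()]).
#' @param shape `"sphere"`, a numeric aspect ratio, or an `eshelby_tensor`.
#' @param n_starts Number of local-optimisation starts (the first is the
#'   closed-form estimate; the rest are deterministic points spread over
#'   the box).
#' @param nu_barrier `c(knee, weight)` of a one-sided quadratic barrier
#'   `weight * max(nu_i - knee, 0)^2` added to the (scale-normalised)
#'   cost. Poisson's ratios above ~0.45 are barely identifiable — the
#'   eigenstrain mismatch becomes flat while downstream quantities blow up
#'   towards the incompressible limit — so the barrier keeps the estimate
#'   a continuous function of the data there instead of snapping to the
#'   box edge. It is exactly zero at and below the knee.
#' @return List with `E_i`, `nu_i`, `cost` (final objective), and
#'   `boundary` (TRUE when the solution sits on the box edge, with a
#'   warning).
#' @export
invert_inclusion <- function(eps_in, eps_bg, E_b, nu_b, shape = "sphere",
                             n_starts = 5, nu_barrier = c(0.45, 10)) {
  if (!all(is.finite(c(eps_in, eps_bg)))) stop("strain inputs must be finite")
  S <- resolve_tensor(shape, nu_b)
  Sn <- normal_block(S)
  Cb <- stiffness_normal(E_b, nu_b)
  eps0 <- c(eps_bg[2], eps_bg[2], -eps_bg[1])     # signed: compression negative
  epsi <- c(eps_in[2], eps_in[2], -eps_in[1])
  eg <- eigenstrain_geometric(Sn, epsi, eps0)
  scale2 <- sum(eg^2) + 1e-30

  cost <- function(p) {
    em <- eigenstrain_material(Sn, Cb, exp(p[1]) * E_b, p[2], eps0)
    sum((eg - em)^2) / scale2 +
      nu_barrier[2] * max(p[2] - nu_barrier[1], 0)^2
  }

  # closed-form start: solve C_i v = w for (lambda_i, mu_i)
  v <- eps0 + Sn %*% eg
  wv <- Cb %*% (v - eg)
  starts <- list()
  if (abs(v[1] - v[3]) > 1e-14) {
    mu <- (wv[1] - wv[3]) / (2 * (v[1] - v[3]))
    la <- (wv[1] - 2 * mu * v[1]) / sum(v)
    nu0 <- la / (2 * (la + mu))
    E0 <- 2 * mu * (1 + nu0)
    if (is.finite(E0) && is.finite(nu0)) {
      E0 <- min(max(E0, 0.05 * E_b), 50 * E_b)
      nu0 <- min(max(nu0, 0.01), 0.499)
      starts[[1]] <- c(log(E0 / E_b), nu0)
    }
  }
  extra <- cbind(log(c(0.5, 1, 2, 5, 10, 0.2, 20)),
                 c(0.25, 0.4, 0.15, 0.3, 0.45, 0.35, 0.2))
  for (i in seq_len(max(0, n_starts - length(starts))))
    starts[[length(starts) + 1]] <- extra[(i - 1) %% nrow(extra) + 1, ]

  lower <- c(log(0.05), 0.01); upper <- c(log(50), 0.499)
  best <- NULL
  for (s in starts) {
    o <- tryCatch(
      stats::optim(s, cost, method = "L-BFGS-B", lower = lower, upper = upper,
                   control = list(factr = 10, maxit = 500)),
      error = function(e) NULL)
    if (!is.null(o) && (is.null(best) || o$value < best$value)) best <- o
  }
  if (is.null(best)) stop("inclusion modulus inversion failed to converge")
  p <- best$par
  on_edge <- any(abs(p - lower) < 1e-6) || any(abs(p - upper) < 1e-6)
  if (on_edge)
    warning("modulus inversion converged on the search-box boundary; ",
            "estimates may be unreliable")
  list(E_i = exp(p[1]) * E_b, nu_i = p[2], cost = best$value * scale2,
       boundary = on_edge)
}

# Per-pixel inversion over an inclusion mask. eta_zz/eta_rr are steady-state
# strain maps (imaging convention); background strains and moduli are shared.
# Uses the closed-form start plus one local refinement per pixel, collapsing
# duplicate (eta_zz, eta_rr) pairs.
invert_inclusion_map <- function(eta_zz, eta_rr, mask, eps_bg, E_b, nu_b,
                                 shape = "sphere") {
  S <- resolve_tensor(shape, nu_b)
  idx <- which(mask & is.finite(eta_zz) & is.finite(eta_rr))
  zz <- eta_zz[idx]; rr <- eta_rr[idx]
  key <- paste(zz, rr)
  grp <- match(key, key)
  uniq <- which(grp == seq_along(idx))
  E_map <- nu_map <- matrix(NA_real_, nrow(eta_zz), ncol(eta_zz))
  Eu <- nuu <- rep(NA_real_, length(uniq))
  for (j in seq_along(uniq)) {
    k <- uniq[j]
    est <- tryCatch(
      suppressWarnings(invert_inclusion(c(zz[k], rr[k]), eps_bg, E_b, nu_b,
                                        shape = S, n_starts = 2)),
      error = function(e) NULL)
    if (!is.null(est)) { Eu[j] <- est$E_i; nuu[j] <- est$nu_i }
  }
  ridx <- match(grp, uniq)
  E_map[idx] <- Eu[ridx]
  nu_map[idx] <- nuu[ridx]
  list(E = E_map, nu = nu_map)
}

#' Best-fit ellipse of a pixel mask
#'
#' Principal-axis decomposition of the mask's second central moments; the
#' semi-axes are scaled so the ellipse area equals the mask area.
#'
#' @param mask Logical matrix (rows = axial, columns = lateral) with at
#'   least 10 TRUE pixels.
#' @param pixel_spacing_mm Pixel size `c(axial, lateral)` in mm (scalar is
#'   recycled).
#' @return List with `l1_mm` (minor semi-axis), `l2_mm` (major semi-axis),
#'   `orientation` (radians of the major axis from the lateral axis, mod
#'   pi), `center_mm` (lateral, axial), and `aspect_axial_lateral` (ratio
#'   of the axis-aligned axial to lateral extents, used to pick the Eshelby
#'   tensor).
#' @export
fit_ellipsoid <- function(mask, pixel_spacing_mm = c(1, 1)) {
  stopifnot(is.logical(mask))
  if (length(pixel_spacing_mm) == 1) pixel_spacing_mm <- rep(pixel_spacing_mm, 2)
  idx <- which(mask, arr.ind = TRUE)
  if (nrow(idx) < 10) stop("mask must contain at least 10 pixels")
  ax <- idx[, 1] * pixel_spacing_mm[1]
  lat <- idx[, 2] * pixel_spacing_mm[2]
  Cv <- stats::cov(cbind(lat, ax))
  if (!all(is.finite(Cv)) || det(Cv) <= 0) stop("degenerate (collinear) mask")
  eg <- eigen(Cv, symmetric = TRUE)
  semi <- 2 * sqrt(eg$values)       # uniform ellipse: cov eigenvalue = (semi/2)^2
  area <- nrow(idx) * prod(pixel_spacing_mm)
  s <- sqrt(area / (pi * semi[1] * semi[2]))
  semi <- semi * s
  orient <- atan2(eg$vectors[2, 1], eg$vectors[1, 1]) %% pi
  aspect <- 2 * sqrt(Cv["ax", "ax"]) * s / (2 * sqrt(Cv["lat", "lat"]) * s)
  list(l1_mm = min(semi), l2_mm = max(semi), orientation = orient,
       center_mm = c(lateral = mean(lat), axial = mean(ax)),
       aspect_axial_lateral = aspect)
}
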