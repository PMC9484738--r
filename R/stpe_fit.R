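# The central estimator: from a creep strain-field series to Young's
# modulus, Poisson's ratio and vascular permeability of the inclusion,
# optionally restricted to a short window of observation.

# Background region of interest: pixels well outside the (enlarged)
# inclusion ellipse and away from the image borders.
background_roi <- function(series, enlarge = 1.6, border_frac = 0.12) {
  d <- dim(series$axial)
  sp <- series$pixel_spacing_mm
  geom <- series$geometry
  ax_mm <- (seq_len(d[1]) - 0.5) * sp[1]
  lat_mm <- (seq_len(d[2]) - 0.5) * sp[2]
  roi <- matrix(TRUE, d[1], d[2])
  if (!is.null(geom)) {
    rr <- outer(ax_mm, lat_mm, function(z, x)
      ((x - geom$center_mm[1]) / (enlarge * geom$semi_axis_lateral_mm))^2 +
        ((z - geom$center_mm[2]) / (enlarge * geom$semi_axis_axial_mm))^2)
    roi <- rr > 1
  } else {
    roi <- !series$mask
  }
  vm <- series$valid_margin
  if (is.null(vm)) {
    nb1 <- ceiling(border_frac * d[1])
    vm <- list(top = nb1, bottom = nb1,
               left = ceiling(border_frac * d[2]),
               right = ceiling(border_frac * d[2]))
  }
  roi[c(seq_len(vm$top), d[1] - seq_len(vm$bottom) + 1), ] <- FALSE
  roi[, c(seq_len(vm$left), d[2] - seq_len(vm$right) + 1)] <- FALSE
  roi
}

# Interior core of the inclusion: the ellipse scaled down, or (without
# geometry) a morphological erosion. Used for the scalar region curves so
# that boundary pixels blurred by the strain kernels do not bias them.
inclusion_core <- function(series, mask, scale = 0.65) {
  geom <- series$geometry
  if (!is.null(geom)) {
    d <- dim(series$axial)
    sp <- series$pixel_spacing_mm
    ax_mm <- (seq_len(d[1]) - 0.5) * sp[1]
    lat_mm <- (seq_len(d[2]) - 0.5) * sp[2]
    core <- outer(ax_mm, lat_mm, function(z, x)
      ((x - geom$center_mm[1]) / (scale * geom$semi_axis_lateral_mm))^2 +
        ((z - geom$center_mm[2]) / (scale * geom$semi_axis_axial_mm))^2 <= 1)
  } else {
    core <- mask
    n_it <- ceiling((1 - scale) * sqrt(sum(mask) / pi))
    for (i in seq_len(n_it)) {
      nb <- (core[pmax(row(core) - 1, 1) + (col(core) - 1) * nrow(core)] &
               core[pmin(row(core) + 1, nrow(core)) + (col(core) - 1) * nrow(core)] &
               core[row(core) + (pmax(col(core) - 1, 1) - 1) * nrow(core)] &
               core[row(core) + (pmin(col(core) + 1, ncol(core)) - 1) * nrow(core)])
      core <- core & matrix(nb, nrow(core), ncol(core))
    }
  }
  if (sum(core & mask) >= 9) core & mask else mask
}

# One full window-restricted estimation pass. Returns parameter maps and
# ROI-scalar estimates.
stpe_window_fit <- function(series, window_s, mask, bg_roi, sigma0, SV,
                            aspect, n_modes, tau_smooth_half = 2) {
  ser_raw <- truncate_series(series, window_s)
  nt <- length(ser_raw$times)
  ser <- if (n_modes >= 1 && n_modes < nt) eof_denoise(ser_raw, n_modes)
  else ser_raw
  maps <- fit_field(ser, window_len_s = window_s, mask = mask | bg_roi)

  # medians: variable-projection steady states have heavy tails on noisy
  # near-flat pixel curves
  eps_bg <- c(stats::median(maps$eta[bg_roi], na.rm = TRUE),
              stats::median(maps$eta_lateral[bg_roi], na.rm = TRUE))
  bm <- background_moduli(sigma0, eps_bg[1], eps_bg[2])
  tensor <- eshelby_tensor_spheroid(bm$nu_b, aspect)

  inv_maps <- invert_inclusion_map(maps$eta, maps$eta_lateral, mask, eps_bg,
                                   bm$E_b, bm$nu_b, shape = tensor)
  tau_map <- replace_tc_outliers(maps$tau, mask)
  tau_map <- masked_median_filter(tau_map, mask, tau_smooth_half)
  vp <- vp_map(tau_map, inv_maps$E, pmin(inv_maps$nu, 0.45), SV, mask)

  # scalar estimates from raw region-mean curves: spatial averaging before
  # the nonlinear fit is far more stable than medians of per-pixel fits,
  # and needs no EOF truncation (which can distort a short transient)
  d <- dim(ser_raw$axial)
  region_curve <- function(stack, region)
    colMeans(matrix(stack, d[1] * d[2], d[3])[which(region), , drop = FALSE])
  core <- inclusion_core(ser_raw, mask)
  # the time constant comes from the whole-mask mean axial curve: mixing
  # with the (transient-free) background axial strain rescales the
  # amplitude but not the rate, and the larger average is quieter
  fit_mask_ax <- varpro_fit(ser_raw$times, region_curve(ser_raw$axial, mask))
  fit_in_ax <- varpro_fit(ser_raw$times, region_curve(ser_raw$axial, core))
  fit_bg_ax <- varpro_fit(ser_raw$times, region_curve(ser_raw$axial, bg_roi))
  fit_bg_lat <- varpro_fit(ser_raw$times, region_curve(ser_raw$lateral, bg_roi))
  tau_scal <- if (fit_mask_ax$degenerate || !is.finite(fit_mask_ax$tau))
    stats::median(tau_map[mask], na.rm = TRUE) else fit_mask_ax$tau
  # the inclusion lateral steady state is solved with the (well-determined)
  # axial time constant imposed: both strains of a region share tau
  eta_fixed_tau <- function(y, tau) {
    B <- cbind(1, exp(-ser_raw$times / tau))
    drop(qr.solve(B, y))[1]
  }
  eta_lat_in <- if (is.finite(tau_scal))
    eta_fixed_tau(region_curve(ser_raw$lateral, core), tau_scal)
  else varpro_fit(ser_raw$times, region_curve(ser_raw$lateral, core))$eta
  eps_bg_c <- c(fit_bg_ax$eta, fit_bg_lat$eta)
  bm_c <- background_moduli(sigma0, eps_bg_c[1], eps_bg_c[2])
  eps_in <- c(fit_in_ax$eta, eta_lat_in)
  # partial-volume correction: the measured core curve mixes inclusion and
  # background through the strain-estimator smoothing; unmix with the
  # known coefficients (see track_rf_series)
  if (!is.null(series$mix)) {
    a_ax <- mean(series$mix$axial[core])
    a_lat <- mean(series$mix$lateral[core])
    if (is.finite(a_ax) && a_ax > 0.2)
      eps_in[1] <- (eps_in[1] - (1 - a_ax) * fit_bg_ax$eta) / a_ax
    if (is.finite(a_lat) && a_lat > 0.2)
      eps_in[2] <- (eps_in[2] - (1 - a_lat) * fit_bg_lat$eta) / a_lat
  }
  tensor_c <- eshelby_tensor_spheroid(bm_c$nu_b, aspect)
  scal <- suppressWarnings(
    invert_inclusion(eps_in, eps_bg_c, bm_c$E_b, bm_c$nu_b, shape = tensor_c))
  if (scal$nu_i >= 0.4985) {
    # Poisson's ratio saturated at the incompressible limit: the lateral
    # mismatch carries no usable information there, so refit the Young's
    # modulus from the axial eigenstrain component alone
    Sn <- normal_block(tensor_c)
    Cb <- stiffness_normal(bm_c$E_b, bm_c$nu_b)
    eps0_s <- c(eps_bg_c[2], eps_bg_c[2], -eps_bg_c[1])
    eg <- eigenstrain_geometric(Sn, c(eps_in[2], eps_in[2], -eps_in[1]), eps0_s)
    o <- stats::optimize(function(le) {
      em <- eigenstrain_material(Sn, Cb, exp(le) * bm_c$E_b, scal$nu_i, eps0_s)
      (eg[3] - em[3])^2
    }, c(log(0.05), log(50)), tol = 1e-12)
    scal$E_i <- exp(o$minimum) * bm_c$E_b
  }
  # H_A has a pole at nu = 0.5; beyond 0.45 the permeability scale is not
  # identifiable at realistic noise, so its evaluation is capped there
  Lp <- vascular_permeability(tau_scal, scal$E_i, min(scal$nu_i, 0.45), SV)

  list(maps = list(eta = maps$eta, eta_lateral = maps$eta_lateral,
                   alpha = maps$alpha, tau = tau_map,
                   E = inv_maps$E, nu = inv_maps$nu, vp = vp),
       fits = maps,
       scalars = list(E_i = scal$E_i, nu_i = scal$nu_i, E_b = bm_c$E_b,
                      nu_b = bm_c$nu_b, tau_s = tau_scal, Lp = as.numeric(Lp),
                      cost = scal$cost),
       eps_in = eps_in, eps_bg = eps_bg_c, window_s = window_s)
}

#' Fit the poroelastic inclusion model to a creep strain series
#'
#' The full estimation pipeline on one window of observation: optional
#' empirical-orthogonal-function denoising, per-pixel variable-projection
#' fitting of the first-order creep model, background moduli from the
#' far-field steady state, inclusion Young's modulus and Poisson's ratio by
#' Eshelby cost-function inversion (per pixel and for the mask-averaged
#' strains), and vascular permeability from the fitted time constant.
#'
#' @param series A `strain_series` (from [generate_strain_series()],
#'   [track_rf_series()] or [read_strain_series()]).
#' @param sigma0 Applied stress magnitude, Pa (defaults to the value stored
#'   in the series).
#' @param mask Logical inclusion mask (defaults to the series mask).
#' @param window_s Window of observation in seconds (default: full record).
#' @param SV Capillary surface-to-volume ratio, m^-1; when `NULL`, taken
#'   from the series or, failing that, derived from the fitted ellipsoid
#'   via [surface_to_volume()].
#' @param n_modes EOF modes kept in denoising (0 disables).
#' @param shape `"auto"` (aspect ratio from the best-fit ellipse of the
#'   mask) or `"sphere"`.
#' @return An object of class `stpe_fit` with `coef`, `print`, `summary`,
#'   `predict`, `fitted`, `residuals`, `plot` and `simulate` methods.
#'   Components include `coefficients` (E_i, nu_i, E_b, nu_b, tau_s, Lp),
#'   per-pixel `maps`, and the mask-mean strain curves in `roi_curves`.
#' @examples
#' bg <- material_params(1e4, 0.3, Lp = 2.5e-10)
#' inc <- material_params(2e4, 0.4, Lp = 1.2e-10)
#' ph <- phantom_spec(inc, bg, grid_mm = 0.5)
#' fit <- stpe_fit(generate_strain_series(ph))
#' coef(fit)
#' @export
stpe_fit <- function(series, sigma0 = series$sigma0_pa, mask = series$mask,
                     window_s = max(series$times), SV = NULL, n_modes = 3,
                     shape = c("auto", "sphere")) {
  stopifnot(inherits(series, "strain_series"))
  shape <- match.arg(shape)
  cl <- match.call()
  bg_roi <- background_roi(series)
  sp <- series$pixel_spacing_mm
  ell <- fit_ellipsoid(mask, sp)
  aspect <- if (shape == "sphere") 1 else ell$aspect_axial_lateral
  if (is.null(SV)) {
    SV <- if (!is.null(series$SV_m1)) series$SV_m1
    else surface_to_volume(ell$l1_mm, ell$l2_mm)$SV_m1
  }
  w <- stpe_window_fit(series, window_s, mask, bg_roi, sigma0, SV, aspect,
                       n_modes)
  # mask-mean observed curves for the curve-level methods
  d <- dim(series$axial)
  idx <- which(mask)
  obs_ax <- apply(matrix(series$axial, d[1] * d[2], d[3])[idx, , drop = FALSE], 2, mean)
  obs_lat <- apply(matrix(series$lateral, d[1] * d[2], d[3])[idx, , drop = FALSE], 2, mean)
  keep <- series$times <= window_s + 1e-9
  fit_ax <- varpro_fit(series$times[keep], obs_ax[keep])
  fit_lat <- varpro_fit(series$times[keep], obs_lat[keep])
  structure(list(call = cl, coefficients = unlist(w$scalars[c(
    "E_i", "nu_i", "E_b", "nu_b", "tau_s", "Lp")]),
    maps = w$maps, window_s = window_s, times = series$times,
    roi_curves = list(axial = obs_ax, lateral = obs_lat),
    curve_fits = list(axial = fit_ax, lateral = fit_lat),
    eps_in = w$eps_in, eps_bg = w$eps_bg, ellipsoid = ell, aspect = aspect,
    SV_m1 = SV, sigma0_pa = sigma0, mask = mask, n_modes = n_modes,
    cost = w$scalars$cost, pixel_spacing_mm = sp,
    geometry = series$geometry), class = "stpe_fit")
}

#' @export
print.stpe_fit <- function(x, digits = 4, ...) {
  cat("Short-time poroelastography fit\n\n")
  cat("Call: ", deparse(x$call), "\n\n")
  cat(sprintf("Window of observation: %.3g s (%d frames)\n",
              x$window_s, sum(x$times <= x$window_s + 1e-9)))
  cat("Coefficients:\n")
  print(signif(x$coefficients, digits))
  invisible(x)
}

#' @export
coef.stpe_fit <- function(object, ...) object$coefficients

#' @export
summary.stpe_fit <- function(object, ...) {
  m <- object$maps
  qs <- function(M) stats::quantile(M[object$mask], c(0.25, 0.5, 0.75), na.rm = TRUE)
  out <- list(call = object$call, coefficients = object$coefficients,
              window_s = object$window_s,
              n_mask = sum(object$mask),
              map_quartiles = rbind(E_i = qs(m$E), nu_i = qs(m$nu),
                                    tau_s = qs(m$tau), Lp = qs(m$vp)),
              ellipsoid = object$ellipsoid, aspect = object$aspect,
              SV_m1 = object$SV_m1, sigma0_pa = object$sigma0_pa,
              curve_rss = c(axial = object$curve_fits$axial$rss,
                            lateral = object$curve_fits$lateral$rss),
              cost = object$cost)
  class(out) <- "summary.stpe_fit"
  out
}

#' @export
print.summary.stpe_fit <- function(x, digits = 4, ...) {
  cat("Short-time poroelastography fit\n\n")
  cat("Call: ", deparse(x$call), "\n\n")
  cat(sprintf("Window %.3g s; %d inclusion pixels; sigma0 = %.4g Pa; S/V = %.4g 1/m\n",
              x$window_s, x$n_mask, x$sigma0_pa, x$SV_m1))
  cat(sprintf("Best-fit ellipse: %.3g x %.3g mm semi-axes (aspect %.3g)\n\n",
              x$ellipsoid$l1_mm, x$ellipsoid$l2_mm, x$aspect))
  cat("Scalar estimates (mask-mean strains):\n")
  print(signif(x$coefficients, digits))
  cat("\nPer-pixel map quartiles (inclusion):\n")
  print(signif(x$map_quartiles, digits))
  cat(sprintf("\nROI curve residual sum of squares: axial %.3g, lateral %.3g\n",
              x$curve_rss[1], x$curve_rss[2]))
  invisible(x)
}

#' Predicted mask-mean strain curves of a fitted creep model
#'
#' @param object An `stpe_fit`.
#' @param times Times at which to evaluate, s.
#' @param ... Unused.
#' @return Data frame with `time_s`, `axial`, `lateral` model curves.
#' @export
predict.stpe_fit <- function(object, times = object$times, ...) {
  ev <- function(f) {
    if (f$degenerate) rep(f$eta, length(times))
    else f$eta + (f$alpha - f$eta) * exp(-times / f$tau)
  }
  data.frame(time_s = times, axial = ev(object$curve_fits$axial),
             lateral = ev(object$curve_fits$lateral))
}

#' @export
fitted.stpe_fit <- function(object, ...) {
  keep <- object$times <= object$window_s + 1e-9
  predict(object, object$times[keep])
}

#' @export
residuals.stpe_fit <- function(object, ...) {
  keep <- object$times <= object$window_s + 1e-9
  pr <- predict(object, object$times[keep])
  data.frame(time_s = object$times[keep],
             axial = object$roi_curves$axial[keep] - pr$axial,
             lateral = object$roi_curves$lateral[keep] - pr$lateral)
}

#' Plot the observed and fitted mask-mean strain curves
#'
#' @param x An `stpe_fit`.
#' @param ... Passed to [graphics::plot()].
#' @export
plot.stpe_fit <- function(x, ...) {
  obs <- x$roi_curves
  pr <- predict(x, x$times)
  graphics::plot(x$times, obs$axial, pch = 16, cex = 0.4,
                 xlab = "time (s)", ylab = "strain",
                 ylim = range(obs$axial, obs$lateral, pr$axial, pr$lateral),
                 ...)
  graphics::points(x$times, obs$lateral, pch = 16, cex = 0.4, col = "grey50")
  graphics::lines(pr$time_s, pr$axial, col = 2, lwd = 2)
  graphics::lines(pr$time_s, pr$lateral, col = 4, lwd = 2)
  graphics::abline(v = x$window_s, lty = 3)
  graphics::legend("right", legend = c("axial (obs)", "lateral (obs)",
                                       "axial (fit)", "lateral (fit)", "window"),
                   pch = c(16, 16, NA, NA, NA), lty = c(NA, NA, 1, 1, 3),
                   col = c(1, "grey50", 2, 4, 1), bty = "n", cex = 0.8)
  invisible(x)
}

#' Simulate strain series from a fitted model
#'
#' Regenerates phantom strain movies from the fitted coefficients through
#' the analytic forward model (the fitted geometry, moduli and vascular
#' permeability define a [phantom_spec()]), optionally with added noise.
#'
#' @param object An `stpe_fit`.
#' @param nsim Number of series to simulate.
#' @param seed Integer seed.
#' @param snr_db Strain-domain SNR of added noise (`Inf` = noise free).
#' @param ... Unused.
#' @return A list of `strain_series` (length `nsim`).
#' @export
simulate.stpe_fit <- function(object, nsim = 1, seed = 1, snr_db = Inf, ...) {
  co <- object$coefficients
  geom <- object$geometry
  if (is.null(geom))
    geom <- list(center_mm = unname(object$ellipsoid$center_mm[c("lateral", "axial")]),
                 semi_axis_lateral_mm = object$ellipsoid$l1_mm,
                 semi_axis_axial_mm = object$ellipsoid$l2_mm)
  d <- dim(object$maps$eta)
  sp <- object$pixel_spacing_mm
  Lp_b <- co[["Lp"]]   # background transport is not identified; reuse inclusion value
  spec <- phantom_spec(
    inclusion = material_params(co[["E_i"]], min(co[["nu_i"]], 0.499),
                                Lp = co[["Lp"]]),
    background = material_params(co[["E_b"]], min(co[["nu_b"]], 0.499), Lp = Lp_b),
    plane_lateral_mm = d[2] * sp[2], plane_axial_mm = d[1] * sp[1],
    inclusion_shape = if (abs(object$aspect - 1) < 0.05) "sphere" else "spheroid",
    semi_axis_lateral_mm = geom$semi_axis_lateral_mm,
    semi_axis_axial_mm = if (abs(object$aspect - 1) < 0.05)
      geom$semi_axis_lateral_mm else geom$semi_axis_axial_mm,
    center_mm = geom$center_mm,
    SV = object$SV_m1, sigma0 = object$sigma0_pa,
    duration_s = max(object$times), dt_s = min(diff(object$times)),
    grid_mm = sp[1])
  out <- vector("list", nsim)
  for (i in seq_len(nsim)) {
    ser <- generate_strain_series(spec)
    if (is.finite(snr_db)) ser <- add_strain_noise(ser, snr_db, seed + i - 1)
    out[[i]] <- ser
  }
  out
}
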