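# Synthetic phantom forward model: piecewise-uniform Eshelby steady states
# plus first-order exponential creep transients on a pixel grid.

#' Phantom specification for a creep-compression experiment
#'
#' Describes the imaged plane (axial x lateral), the embedded inclusion
#' (sphere or axisymmetric spheroid), the materials of both regions, the
#' applied stress and the acquisition timing.
#'
#' @param inclusion,background [material_params()] for the two regions.
#' @param plane_lateral_mm,plane_axial_mm Extent of the imaged plane, mm.
#' @param inclusion_shape `"sphere"` or `"spheroid"`.
#' @param semi_axis_lateral_mm,semi_axis_axial_mm Inclusion semi-axes, mm.
#'   For a sphere both default to 3.75 mm (7.5 mm diameter).
#' @param center_mm Inclusion center `(lateral, axial)` in mm; defaults to
#'   the plane center.
#' @param SV Capillary surface-area-to-volume ratio, m^-1.
#' @param sigma0 Applied axial stress magnitude, Pa (compression).
#' @param duration_s,dt_s Record length and sampling interval, s.
#' @param grid_mm Pixel size, mm.
#' @return A `phantom_spec` object.
#' @export
phantom_spec <- function(inclusion, background,
                         plane_lateral_mm = 20, plane_axial_mm = 40,
                         inclusion_shape = c("sphere", "spheroid"),
                         semi_axis_lateral_mm = 3.75,
                         semi_axis_axial_mm = if (match.arg(inclusion_shape) == "sphere")
                           semi_axis_lateral_mm else 2.5,
                         center_mm = c(plane_lateral_mm / 2, plane_axial_mm / 2),
                         SV = 20000, sigma0 = 1000,
                         duration_s = 60, dt_s = 0.1, grid_mm = 0.1) {
  inclusion_shape <- match.arg(inclusion_shape)
  stopifnot(inherits(inclusion, "material_params"),
            inherits(background, "material_params"))
  if (inclusion_shape == "sphere" && semi_axis_axial_mm != semi_axis_lateral_mm)
    stop("a spherical inclusion must have equal semi-axes")
  if (sigma0 <= 0) stop("sigma0 must be a positive compression magnitude")
  if (duration_s / dt_s < 10) stop("duration_s/dt_s must yield at least 10 samples")
  if (center_mm[1] - semi_axis_lateral_mm < 0 ||
      center_mm[1] + semi_axis_lateral_mm > plane_lateral_mm ||
      center_mm[2] - semi_axis_axial_mm < 0 ||
      center_mm[2] + semi_axis_axial_mm > plane_axial_mm)
    stop("inclusion does not fit inside the imaged plane")
  structure(list(
    plane_lateral_mm = plane_lateral_mm, plane_axial_mm = plane_axial_mm,
    inclusion_shape = inclusion_shape,
    semi_axis_lateral_mm = semi_axis_lateral_mm,
    semi_axis_axial_mm = semi_axis_axial_mm,
    center_mm = center_mm, inclusion = inclusion, background = background,
    SV = SV, sigma0 = sigma0, duration_s = duration_s, dt_s = dt_s,
    grid_mm = grid_mm
  ), class = "phantom_spec")
}

#' @export
print.phantom_spec <- function(x, ...) {
  cat(sprintf("Creep phantom: %g x %g mm plane, %s inclusion %g x %g mm (lat x ax)\n",
              x$plane_lateral_mm, x$plane_axial_mm, x$inclusion_shape,
              2 * x$semi_axis_lateral_mm, 2 * x$semi_axis_axial_mm))
  cat(sprintf("  sigma0 = %g Pa, S/V = %g 1/m, %g s @ %g s, %g mm pixels\n",
              x$sigma0, x$SV, x$duration_s, x$dt_s, x$grid_mm))
  cat("  inclusion: "); print(x$inclusion)
  cat("  background: "); print(x$background)
  invisible(x)
}

new_strain_series <- function(times, axial, lateral, mask, pixel_spacing_mm,
                              sigma0_pa, SV_m1, geometry = NULL, truth = NULL) {
  stopifnot(all(dim(axial) == dim(lateral)),
            length(times) == dim(axial)[3],
            all(dim(mask) == dim(axial)[1:2]),
            all(diff(times) > 0))
  if (length(pixel_spacing_mm) == 1) pixel_spacing_mm <- rep(pixel_spacing_mm, 2)
  structure(list(times = times, axial = axial, lateral = lateral, mask = mask,
                 pixel_spacing_mm = pixel_spacing_mm, sigma0_pa = sigma0_pa,
                 SV_m1 = SV_m1, geometry = geometry, truth = truth),
            class = "strain_series")
}

#' @export
print.strain_series <- function(x, ...) {
  d <- dim(x$axial)
  cat(sprintf("Strain-field series: %d x %d pixels (axial x lateral), %d frames over %.3g s\n",
              d[1], d[2], d[3], max(x$times)))
  cat(sprintf("  pixel spacing %.4g x %.4g mm, sigma0 = %.4g Pa, S/V = %.4g 1/m\n",
              x$pixel_spacing_mm[1], x$pixel_spacing_mm[2], x$sigma0_pa, x$SV_m1))
  cat(sprintf("  inclusion mask: %d pixels\n", sum(x$mask)))
  invisible(x)
}

#' Generate the ground-truth strain movie of a phantom
#'
#' Per region, each strain component follows the first-order creep model
#' `s(t) = eta + (alpha - eta) exp(-t / tau)`. The steady state `eta` comes
#' from the equivalent-inclusion (Eshelby) solution at the drained Poisson's
#' ratios; the instantaneous response `alpha` from the same solution with
#' both regions at an effective undrained `nu = 0.499` (same Young's
#' moduli); `tau` from [strain_time_constant()] of each region's own
#' material. Axial strains are stored compression-positive, lateral strains
#' expansion-positive.
#'
#' @param spec A [phantom_spec()].
#' @param nu_undrained Effective Poisson's ratio of the instantaneous
#'   (undrained) response; slightly below 0.5 to keep moduli finite.
#' @return A `strain_series` object with the time stamps, axial and lateral
#'   strain stacks (`axial x lateral x time` arrays), the inclusion mask,
#'   and a `truth` list holding the per-region model parameters used.
#' @export
generate_strain_series <- function(spec, nu_undrained = 0.499) {
  stopifnot(inherits(spec, "phantom_spec"))
  aspect <- spec$semi_axis_axial_mm / spec$semi_axis_lateral_mm
  shape <- if (abs(aspect - 1) < 1e-12) "sphere" else aspect

  # drained steady state and undrained instantaneous response
  drained <- eshelby_forward_strain(spec$background, spec$inclusion, shape,
                                    spec$sigma0, aspect = aspect)
  bg_u <- material_params(spec$background$E, nu_undrained)
  inc_u <- material_params(spec$inclusion$E, nu_undrained)
  undrained <- eshelby_forward_strain(bg_u, inc_u, shape, spec$sigma0,
                                      aspect = aspect)

  a_m <- spec$semi_axis_lateral_mm * 1e-3
  tau_in <- strain_time_constant(spec$inclusion, spec$SV, a = a_m)
  tau_bg <- withCallingHandlers(
    strain_time_constant(spec$background, spec$SV, a = a_m),
    warning = function(w) invokeRestart("muffleWarning"))

  g <- spec$grid_mm
  lat <- seq(g / 2, spec$plane_lateral_mm - g / 2, by = g)
  ax <- seq(g / 2, spec$plane_axial_mm - g / 2, by = g)
  mask <- outer(ax, lat, function(z, x)
    ((x - spec$center_mm[1]) / spec$semi_axis_lateral_mm)^2 +
      ((z - spec$center_mm[2]) / spec$semi_axis_axial_mm)^2 <= 1)
  times <- seq(0, spec$duration_s, by = spec$dt_s)

  build <- function(alpha_in, eta_in, alpha_bg, eta_bg) {
    arr <- array(0, dim = c(length(ax), length(lat), length(times)))
    cin <- eta_in + (alpha_in - eta_in) * exp(-times / tau_in)
    cbg <- eta_bg + (alpha_bg - eta_bg) * exp(-times / tau_bg)
    for (k in seq_along(times)) {
      frame <- matrix(cbg[k], length(ax), length(lat))
      frame[mask] <- cin[k]
      arr[, , k] <- frame
    }
    arr
  }
  axial_arr <- build(undrained$eps_zz_in, drained$eps_zz_in,
                     undrained$eps_zz_bg, drained$eps_zz_bg)
  lateral_arr <- build(undrained$eps_rr_in, drained$eps_rr_in,
                       undrained$eps_rr_bg, drained$eps_rr_bg)

  truth <- list(
    eta_zz_in = drained$eps_zz_in, eta_rr_in = drained$eps_rr_in,
    eta_zz_bg = drained$eps_zz_bg, eta_rr_bg = drained$eps_rr_bg,
    alpha_zz_in = undrained$eps_zz_in, alpha_rr_in = undrained$eps_rr_in,
    alpha_zz_bg = undrained$eps_zz_bg, alpha_rr_bg = undrained$eps_rr_bg,
    tau_in = tau_in, tau_bg = tau_bg,
    E_i = spec$inclusion$E, nu_i = spec$inclusion$nu,
    E_b = spec$background$E, nu_b = spec$background$nu,
    Lp_i = spec$inclusion$Lp, aspect = aspect)
  geometry <- list(center_mm = spec$center_mm,
                   semi_axis_lateral_mm = spec$semi_axis_lateral_mm,
                   semi_axis_axial_mm = spec$semi_axis_axial_mm,
                   aspect = aspect)
  new_strain_series(times, axial_arr, lateral_arr, mask,
                    pixel_spacing_mm = c(g, g), sigma0_pa = spec$sigma0,
                    SV_m1 = spec$SV, geometry = geometry, truth = truth)
}

#' Add Gaussian noise to a strain-field series at a prescribed SNR
#'
#' Zero-mean Gaussian noise is added independently to the axial and lateral
#' stacks, scaled so that `20 log10(rms(signal) / rms(noise))` equals
#' `snr_db`. `snr_db = Inf` returns the series unchanged.
#'
#' @param series A `strain_series`.
#' @param snr_db Target signal-to-noise ratio in dB.
#' @param seed Integer seed; identical seeds give identical output.
#' @return The noisy `strain_series` (with `$snr_db` recorded).
#' @export
add_strain_noise <- function(series, snr_db, seed) {
  stopifnot(inherits(series, "strain_series"), is.finite(seed))
  if (is.infinite(snr_db)) return(series)
  if (!is.finite(snr_db)) stop("snr_db must be finite or +Inf")
  set.seed(as.integer(seed))
  scale <- 10^(-snr_db / 20)
  for (comp in c("axial", "lateral")) {
    x <- series[[comp]]
    sd_n <- sqrt(mean(x^2)) * scale
    series[[comp]] <- x + array(stats::rnorm(length(x), sd = sd_n), dim = dim(x))
  }
  series$snr_db <- snr_db
  series
}

# Truncate a series to t <= window_s (used by the short-window fits).
truncate_series <- function(series, window_s) {
  keep <- series$times <= window_s + 1e-9
  if (sum(keep) < 4) stop("window too short: fewer than 4 samples")
  series$times <- series$times[keep]
  series$axial <- series$axial[, , keep, drop = FALSE]
  series$lateral <- series$lateral[, , keep, drop = FALSE]
  series
}
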