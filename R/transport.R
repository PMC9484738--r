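# Transport-parameter conversions: tumor geometry to capillary S/V, force
# sensor reading to stress, and fitted time constant + moduli to vascular
# permeability.

#' Capillary surface-to-volume ratio from tumor axes
#'
#' The tumor is approximated by its best-fit ellipsoid with minor semi-axis
#' `l1` and major semi-axis `l2` (third axis equal to the minor one), so
#' `Vt = (4/3) pi l1^2 l2` in mm^3, and the capillary wall area per unit
#' volume follows the allometric regression `S/V = 10 f Vt^g` with
#' `f = 54.68` and `g = -0.2021` (`S/V` in cm^-1).
#'
#' @param l1_mm Minor semi-axis, mm.
#' @param l2_mm Major semi-axis, mm.
#' @return List with `Vt_mm3`, `SV_cm1` and `SV_m1`.
#' @examples
#' surface_to_volume(3.75, 3.75) # 7.5 mm sphere: ~1.84e4 m^-1
#' @export
surface_to_volume <- function(l1_mm, l2_mm) {
  if (l1_mm <= 0 || l2_mm <= 0) stop("semi-axes must be positive")
  Vt <- 4 / 3 * pi * l1_mm^2 * l2_mm
  SV_cm1 <- 10 * 54.68 * Vt^(-0.2021)
  list(Vt_mm3 = Vt, SV_cm1 = SV_cm1, SV_m1 = 100 * SV_cm1)
}

#' Applied stress from a force-sensor reading
#'
#' The sensor reports force on a 0-255 scale spanning 0-4.4 N over a
#' sensing area of `7.1331e-5` m^2:
#' `sigma0 = Fr * 4.4 / (255 * Ar)` Pa.
#'
#' @param Fr Raw sensor reading, in `[0, 255]`.
#' @return Applied axial stress, Pa.
#' @examples
#' applied_stress(255) # ~61.7 kPa full scale
#' @export
applied_stress <- function(Fr) {
  if (any(!is.finite(Fr)) || any(Fr < 0 | Fr > 255))
    stop("force reading must lie in [0, 255]")
  Fr * 4.4 / (255 * 7.1331e-5)
}

#' Vascular permeability from the strain time constant and moduli
#'
#' Inverts `tau = 1 / (H_A * Lp * S/V)`:
#' `Lp = 1 / (tau * H_A(E, nu) * S/V)`. Vectorised; `NaN` time constants
#' (degenerate fits) propagate to `NaN`.
#'
#' @param tau_s Strain time constant, s.
#' @param E_pa Young's modulus, Pa.
#' @param nu Poisson's ratio.
#' @param SV_m1 Capillary surface-to-volume ratio, m^-1 (this API accepts
#'   only m^-1; convert cm^-1 values explicitly via
#'   [surface_to_volume()]`$SV_m1` or multiply by 100).
#' @return Vascular permeability in m (Pa s)^-1.
#' @examples
#' vascular_permeability(10, 1e4, 0.3, 2e4) # 3.714e-10
#' @export
vascular_permeability <- function(tau_s, E_pa, nu, SV_m1) {
  if (any(SV_m1 <= 0)) stop("S/V must be positive (in m^-1)")
  bad <- !is.finite(tau_s) | tau_s <= 0
  out <- 1 / (tau_s * aggregate_modulus(E_pa, nu) * SV_m1)
  out[bad] <- NaN
  n_bad <- sum(bad & !is.na(bad))
  if (n_bad > 0) attr(out, "n_degenerate") <- n_bad
  out
}

#' Per-pixel vascular permeability map
#'
#' Applies [replace_tc_outliers()] to the time-constant map inside the
#' inclusion mask and then [vascular_permeability()] pixel-wise. Values are
#' reported only inside the mask, where the vascular-dominance assumption
#' underlying the time-constant model holds; set `background = TRUE` to
#' compute background pixels anyway (with a warning).
#'
#' @param tau_map,E_map,nu_map Aligned images of time constant (s), Young's
#'   modulus (Pa) and Poisson's ratio.
#' @param SV_m1 Capillary surface-to-volume ratio, m^-1.
#' @param mask Logical inclusion mask.
#' @param threshold_s Time-constant outlier threshold passed on.
#' @param background If TRUE also fill background pixels.
#' @return Image of `Lp` in m (Pa s)^-1 (`NA` outside the mask unless
#'   `background = TRUE`).
#' @export
vp_map <- function(tau_map, E_map, nu_map, SV_m1, mask, threshold_s = 100,
                   background = FALSE) {
  stopifnot(all(dim(tau_map) == dim(E_map)), all(dim(tau_map) == dim(nu_map)),
            all(dim(tau_map) == dim(mask)))
  tau_map <- replace_tc_outliers(tau_map, mask, threshold_s)
  out <- matrix(NA_real_, nrow(tau_map), ncol(tau_map))
  sel <- mask
  if (background) {
    warning("computing vascular permeability outside the inclusion: the ",
            "vascular-dominance assumption may not hold in the background")
    sel <- sel | !mask
  }
  out[sel] <- vascular_permeability(tau_map[sel], E_map[sel], nu_map[sel], SV_m1)
  out
}
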