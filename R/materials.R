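#' Material parameters of a poroelastic region
#'
#' Bundles the drained elastic constants and the transport constants of one
#' tissue region (inclusion or background).
#'
#' @param E Young's modulus in Pa. Must be positive.
#' @param nu Drained Poisson's ratio, dimensionless, in `[0, 0.5)`.
#' @param Lp Vascular permeability (hydraulic conductivity of the capillary
#'   walls) in m (Pa s)^-1. Non-negative.
#' @param k Interstitial permeability in m^2 (Pa s)^-1. Non-negative. Only
#'   used for the validity check of the microfiltration-dominance assumption
#'   (see [strain_time_constant()]); the forward model itself assumes
#'   vascular filtration dominates.
#'
#' @return An object of class `material_params` (a named list).
#' @examples
#' tumor <- material_params(E = 2e4, nu = 0.4, Lp = 1.17e-10, k = 1e-14)
#' @export
material_params <- function(E, nu, Lp = 0, k = 0) {
  stopifnot(length(E) == 1L, length(nu) == 1L, length(Lp) == 1L, length(k) == 1L)
  if (!is.finite(E) || E <= 0) stop("Young's modulus E must be positive and finite")
  if (!is.finite(nu) || nu < 0 || nu >= 0.5)
    stop("Poisson's ratio nu must lie in [0, 0.5)")
  if (!is.finite(Lp) || Lp < 0) stop("vascular permeability Lp must be non-negative")
  if (!is.finite(k) || k < 0) stop("interstitial permeability k must be non-negative")
  structure(list(E = E, nu = nu, Lp = Lp, k = k), class = "material_params")
}

#' @export
print.material_params <- function(x, ...) {
  cat(sprintf(
    "Poroelastic material: E = %.4g Pa, nu = %.4g, Lp = %.4g m/(Pa s), k = %.4g m^2/(Pa s)\n",
    x$E, x$nu, x$Lp, x$k
  ))
  invisible(x)
}

#' Aggregate (confined-compression) modulus
#'
#' `H_A = E (1 - nu) / ((1 - 2 nu) (1 + nu))`, the stiffness of a linear
#' elastic solid under laterally confined compression. `H_A >= E` for all
#' admissible `nu`, with equality at `nu = 0`; it diverges at the
#' incompressible limit `nu = 0.5`.
#'
#' @param E Young's modulus in Pa (vectorised).
#' @param nu Poisson's ratio in `[0, 0.5)` (vectorised). `NA` entries
#'   propagate.
#' @return Aggregate modulus in Pa.
#' @examples
#' aggregate_modulus(10000, 0.3) # 13461.54 Pa
#' @export
aggregate_modulus <- function(E, nu) {
  if (any(E <= 0, na.rm = TRUE)) stop("Young's modulus E must be positive")
  if (any(nu < 0 | nu >= 0.5, na.rm = TRUE))
    stop("nu must lie in [0, 0.5): aggregate modulus diverges at the incompressible limit")
  E * (1 - nu) / ((1 - 2 * nu) * (1 + nu))
}

#' Strain time constant of a creeping poroelastic region
#'
#' Under vascular-filtration-dominated creep (`chi = Lp * S/V` much larger
#' than `k / a^2`), the axial strain relaxes with time constant
#' `tau = 1 / (H_A * chi)`.
#'
#' @param mat A [material_params()] object (`Lp` must be positive).
#' @param SV Surface-area-to-volume ratio of the capillary walls, m^-1.
#' @param a Optional inclusion radius (m) used to check the dominance
#'   assumption `chi >> k / a^2`; a warning is raised when
#'   `chi < 10 * k / a^2`.
#' @return Time constant in seconds.
#' @examples
#' m <- material_params(1e4, 0.3, Lp = 3.7143e-10)
#' strain_time_constant(m, SV = 2e4) # ~10 s
#' @export
strain_time_constant <- function(mat, SV, a = NULL) {
  stopifnot(inherits(mat, "material_params"))
  if (mat$Lp <= 0 || SV <= 0)
    stop("Lp and S/V must be positive: the strain time constant is infinite otherwise")
  chi <- mat$Lp * SV
  if (!is.null(a)) {
    if (a <= 0) stop("inclusion radius a must be positive")
    if (chi < 10 * mat$k / a^2)
      warning("microfiltration-dominance assumption chi >> k/a^2 is questionable ",
              sprintf("(chi = %.3g, k/a^2 = %.3g)", chi, mat$k / a^2))
  }
  1 / (aggregate_modulus(mat$E, mat$nu) * chi)
}
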