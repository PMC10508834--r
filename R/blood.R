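#' Blood rheology and wall properties
#'
#' Bulk blood properties used throughout: density `rho` = 1.055 g/cm^3 and
#' kinematic viscosity `nu` = 3.03e-2 cm^2/s, with a power-law axial velocity
#' profile of exponent `gamma` = 9 (blunt core, no-slip wall). The bulk dynamic
#' viscosity is `mu = rho * nu`.
#'
#' @param density g/cm^3.
#' @param kinematic_viscosity cm^2/s.
#' @param profile_exponent Dimensionless power-law profile exponent.
#' @return A list of class `blood_properties`.
#' @export
#' @examples
#' blood_properties()$mu
blood_properties <- function(density = 1.055,
                             kinematic_viscosity = 3.03e-2,
                             profile_exponent = 9) {
  if (density <= 0 || kinematic_viscosity <= 0 || profile_exponent <= 0) {
    abort("blood properties must be positive")
  }
  structure(
    list(rho = density, nu = kinematic_viscosity, gamma = profile_exponent,
         mu = density * kinematic_viscosity),
    class = "blood_properties"
  )
}

#' Dynamic viscosity of blood in a vessel of given radius
#'
#' In the microvascular structured trees the apparent viscosity depends on
#' vessel calibre (the Fahraeus-Lindqvist effect). Mode `"radius"` uses the
#' Pries-type in-vitro empirical law at discharge hematocrit 0.45,
#' `eta_rel(D) = 220 exp(-1.3 D) + 3.2 - 2.44 exp(-0.06 D^0.645)` with the
#' lumen diameter `D` in micrometres, relative to a plasma viscosity of
#' 0.01 g/cm/s; its large-vessel limit (3.2 cP) matches the bulk viscosity
#' `rho * nu` to about 0.1%. Mode `"constant"` returns the bulk value.
#'
#' @param r Vessel radius in cm (vectorised).
#' @param blood A [blood_properties()] object.
#' @param mode `"radius"` or `"constant"`.
#' @return Dynamic viscosity in g/cm/s.
#' @export
#' @examples
#' viscosity_law(c(0.005, 0.05, 1), mode = "radius")
viscosity_law <- function(r, blood = blood_properties(),
                          mode = c("radius", "constant")) {
  mode <- match.arg(mode)
  if (any(r <= 0)) abort("radius must be positive")
  if (mode == "constant") {
    return(rep(blood$mu, length(r)))
  }
  d_um <- 2 * r * 1e4
  eta_rel <- 220 * exp(-1.3 * d_um) + 3.2 - 2.44 * exp(-0.06 * d_um^0.645)
  0.01 * eta_rel
}
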