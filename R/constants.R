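#' Speed of light in vacuum
#'
#' Declared once and consumed everywhere times and path lengths are
#' interconverted, in cm/ns so that `v = cVacuum() / n` is directly usable
#' with coefficients in 1/cm and times in ns.
#'
#' @return Speed of light in vacuum, cm/ns.
#' @export
cVacuum <- function() 29.9792458

#' Speed of light inside a medium
#'
#' @param nIn refractive index of the medium.
#' @return Phase velocity, cm/ns.
#' @export
lightSpeed <- function(nIn) cVacuum() / nIn

#' Boundary reflection factor for the extrapolated boundary condition
#'
#' The extrapolated zero-fluence plane of diffusion theory sits a distance
#' `z_e = 2 A D` above the physical surface, where `A` accounts for the
#' internal reflections caused by the refractive-index mismatch. `A` is
#' computed from the Groenhuis polynomial approximation to the
#' angle-integrated Fresnel reflectance, a standard choice for
#' tissue/air interfaces.
#'
#' @param nRel relative refractive index `n_in / n_out` (>= 1 for tissue in
#'   air).
#' @return Dimensionless boundary factor `A` (1 for matched boundaries).
#' @export
boundaryReflectionFactor <- function(nRel) {
  stopifnot(is.numeric(nRel), length(nRel) == 1L, is.finite(nRel), nRel > 0)
  if (abs(nRel - 1) < 1e-12) return(1)
  rd <- -1.440 / nRel^2 + 0.710 / nRel + 0.668 + 0.0636 * nRel
  (1 + rd) / (1 - rd)
}
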