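#' Diffuse-layer (Debye) thickness of the electrolyte
#'
#' Characteristic decay length of the ionic atmosphere at the charged
#' interface,
#' \deqn{d = \sqrt{\varepsilon \varepsilon_0 R T / (2 F^2 I)},}
#' with `I` the ionic strength. Scales as \eqn{I^{-1/2}}; about 0.77 nm for a
#' 0.155 M 1:1 salt at 25 degrees C.
#'
#' @param electrolyte An [electrolyte_spec()] object.
#' @return Diffuse-layer thickness, m.
#' @export
#' @examples
#' diffuse_layer_thickness(electrolyte_spec("Na", 155))  # ~7.73e-10 m
diffuse_layer_thickness <- function(electrolyte) {
  stopifnot(inherits(electrolyte, "pcion_electrolyte"))
  I <- electrolyte$ionic_strength
  T <- electrolyte$temperature
  if (!is.finite(I) || I <= 0 || !is.finite(T) || T <= 0) {
    pc_abort("ionic strength and temperature must be positive",
             "pcion_error_invalid_input")
  }
  sqrt(electrolyte$epsilon_r * .pc$eps0 * .pc$R * T / (2 * .pc$Faraday^2 * I))
}

#' Convert electrophoretic mobility to surface charge density
#'
#' The microelectrophoresis conversion \eqn{\sigma = \eta u / d}: measured
#' mobility times solution viscosity over the diffuse-layer thickness. Linear
#' and sign-preserving, so the isoelectric point is the same in mobility and
#' in charge density.
#'
#' @param u Electrophoretic mobility, m\eqn{^2} V\eqn{^{-1}} s\eqn{^{-1}}
#'   (vectorized).
#' @param electrolyte An [electrolyte_spec()] object.
#' @return Surface charge density, C/m\eqn{^2}.
#' @seealso [sigma_to_mobility()] for the exact inverse.
#' @export
mobility_to_sigma <- function(u, electrolyte) {
  electrolyte$eta * u / diffuse_layer_thickness(electrolyte)
}

#' Convert surface charge density to electrophoretic mobility
#'
#' Exact inverse of [mobility_to_sigma()]: \eqn{u = \sigma d / \eta}. Used by
#' the synthetic generator, which applies measurement noise on the mobility
#' scale.
#'
#' @param sigma Surface charge density, C/m\eqn{^2} (vectorized).
#' @inheritParams mobility_to_sigma
#' @return Mobility, m\eqn{^2} V\eqn{^{-1}} s\eqn{^{-1}}.
#' @export
sigma_to_mobility <- function(sigma, electrolyte) {
  sigma * diffuse_layer_thickness(electrolyte) / electrolyte$eta
}
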