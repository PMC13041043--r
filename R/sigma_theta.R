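#' Potential density anomaly at surface pressure
#'
#' Evaluates the UNESCO EOS-80 one-atmosphere equation of state for
#' seawater and returns the potential density anomaly
#' \eqn{\sigma_\theta = \rho(S, T, 0) - 1000} in kg m\eqn{^{-3}}.
#' Salinity and temperature are treated as practical salinity and in-situ
#' temperature at zero pressure; for the upper-ocean ranges relevant to
#' water-mass classification the difference from a TEOS-10 evaluation is
#' well below the envelope resolution.
#'
#' Published check values for the polynomial:
#' \eqn{\rho(0, 5, 0) = 999.96675}, \eqn{\rho(35, 5, 0) = 1027.67547} and
#' \eqn{\rho(35, 25, 0) = 1023.34306} kg m\eqn{^{-3}}.
#'
#' @param salinity practical salinity (dimensionless, 0-45).
#' @param temperature temperature in degrees Celsius (-3 to 40).
#' @return numeric vector of \eqn{\sigma_\theta} values (kg m\eqn{^{-3}}).
#' @examples
#' compute_sigma_theta(35, 5)  # 27.675
#' @export
compute_sigma_theta <- function(salinity, temperature) {
  if (any(!is.finite(salinity)) || any(salinity < 0) || any(salinity > 45)) {
    stop("salinity out of range [0, 45]", call. = FALSE)
  }
  if (any(!is.finite(temperature)) ||
      any(temperature < -3) || any(temperature > 40)) {
    stop("temperature out of range [-3, 40]", call. = FALSE)
  }
  S <- salinity
  T <- temperature
  # density of Standard Mean Ocean Water (Bigg 1967 as adopted in EOS-80)
  rho_w <- 999.842594 + 6.793952e-2 * T - 9.095290e-3 * T^2 +
    1.001685e-4 * T^3 - 1.120083e-6 * T^4 + 6.536332e-9 * T^5
  A <- 8.24493e-1 - 4.0899e-3 * T + 7.6438e-5 * T^2 -
    8.2467e-7 * T^3 + 5.3875e-9 * T^4
  B <- -5.72466e-3 + 1.0227e-4 * T - 1.6546e-6 * T^2
  C <- 4.8314e-4
  rho_w + A * S + B * S^1.5 + C * S^2 - 1000
}
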