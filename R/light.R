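#' Aiba light response
#'
#' Saturation/photoinhibition response `I / (I + ks + I^2/ki)`: it rises from
#' 0 at darkness, peaks at the optimum intensity `sqrt(ks * ki)`, and decays
#' towards 0 at strongly supra-optimal intensity.
#'
#' @param I Local light intensity (umol m^-2 s^-1); non-negative, vectorized.
#' @param response A [photo_response()].
#' @return Dimensionless factor(s) in `[0, 1)`.
#' @export
#' @examples
#' p <- photo_response(165, 457)
#' photoresponse(92, p)
#' photoresponse(sqrt(165 * 457), p)   # the maximum
photoresponse <- function(I, response) {
  stopifnot(inherits(response, "photo_response"))
  if (any(I < 0)) stop("light intensity I must be non-negative")
  I / (I + response$ks + I^2 / response$ki)
}

#' Extinction coefficient of the culture
#'
#' Beer-Lambert extinction from cell absorption plus bubble scattering:
#' `tau_c * (1000 * X) + 3 * alpha_g / d_b`. Biomass enters in g m^-3, hence
#' the factor 1000 on the g L^-1 concentration.
#'
#' @param X Biomass concentration (g L^-1); non-negative, vectorized.
#' @param optics An [optical_params()].
#' @return Extinction coefficient(s) (m^-1).
#' @export
#' @examples
#' attenuation_coefficient(0.5, optical_params())  # cells ~6x bubble term
attenuation_coefficient <- function(X, optics) {
  stopifnot(inherits(optics, "optical_params"))
  if (any(X < 0)) stop("biomass concentration X must be non-negative")
  optics$tau_c * 1000 * X + 3 * optics$alpha_g / optics$d_b
}

#' Local light intensity at depth
#'
#' Exponential decay from each illuminated surface. With two illuminated
#' faces the field is the superposition
#' `I0 * exp(-a*z) + I0 * exp(-a*(L - z))`.
#'
#' @param z Depth from the front (illuminated) surface (m); in `[0, L]`,
#'   vectorized.
#' @param X Biomass concentration (g L^-1).
#' @param optics An [optical_params()].
#' @param light A [light_config()].
#' @return Local intensity (umol m^-2 s^-1).
#' @export
local_intensity <- function(z, X, optics, light) {
  stopifnot(inherits(light, "light_config"))
  if (any(z < 0 | z > light$L))
    stop("depth z must lie within [0, L] = [0, ", light$L, "]")
  a <- attenuation_coefficient(X, optics)
  I <- light$I0 * exp(-a * z)
  if (light$n_surfaces == 2L)
    I <- I + light$I0 * exp(-a * (light$L - z))
  I
}

#' Depth-averaged photoresponse
#'
#' Averages the Aiba response of the local light field over the reactor
#' width by composite trapezoid quadrature:
#' `(1 / (2n)) * (f(I(z0)) + 2*sum f(I(zi)) + f(I(zn)))` on `n` equal
#' intervals. This is the growth factor `kbar(I)` (and, with the hydrogen
#' response, `hbar(I)`) appearing in the kinetic models.
#'
#' The interval count defaults to the configuration's rule (base count,
#' refined with optical depth when `adaptive = TRUE`; see [light_config()]).
#' Passing `n_steps` explicitly forces that fixed count, which serves as a
#' reference quadrature at large `n_steps`.
#'
#' @param X Biomass concentration (g L^-1), a single value.
#' @param optics An [optical_params()].
#' @param light A [light_config()].
#' @param response A [photo_response()].
#' @param n_steps Optional fixed number of trapezoid intervals, overriding
#'   the configuration.
#' @return Dimensionless average response, a single value in `[0, 1)`.
#' @export
#' @examples
#' o <- optical_params(); lc <- light_config(I0 = 457, L = 0.025)
#' depth_averaged_response(12, o, lc, photo_response(165, 457))
#' depth_averaged_response(12, o, lc, photo_response(165, 457), n_steps = 1e4)
depth_averaged_response <- function(X, optics, light, response,
                                    n_steps = NULL) {
  stopifnot(inherits(optics, "optical_params"),
            inherits(light, "light_config"),
            inherits(response, "photo_response"))
  if (length(X) != 1 || !is.finite(X) || X < 0)
    stop("X must be a single non-negative number")
  a <- attenuation_coefficient(X, optics)
  n <- quad_intervals(a, light, n_steps)
  z <- seq(0, light$L, length.out = n + 1)
  I <- light$I0 * exp(-a * z)
  if (light$n_surfaces == 2L) I <- I + rev(I)
  trap_mean(photoresponse(I, response))
}

# Number of trapezoid intervals: base count, refined so the step never
# exceeds half the attenuation length 1/a (boundary-layer resolution).
quad_intervals <- function(a, light, n_steps = NULL) {
  if (!is.null(n_steps)) {
    stopifnot(length(n_steps) == 1, n_steps >= 2, n_steps == round(n_steps))
    return(as.integer(n_steps))
  }
  n <- light$n_steps
  if (light$adaptive) n <- max(n, ceiling(2 * a * light$L))
  as.integer(n)
}

# Composite trapezoid mean of f sampled on an equispaced grid (n+1 points):
# equals (1/L) * integral when multiplied out, i.e. mean with weights
# 1, 2, ..., 2, 1 over 2n.
trap_mean <- function(f) {
  n <- length(f) - 1L
  (f[1L] + 2 * sum(f[seq.int(2L, n)]) + f[n + 1L]) / (2 * n)
}

# Fast path used inside ODE right-hand sides: both the growth and the H2
# depth averages share the attenuation field, so compute the intensities
# once. Returns c(kbar, hbar).
kbar_hbar <- function(X, optics, light, growth_response, h2_response) {
  a <- optics$tau_c * 1000 * X + 3 * optics$alpha_g / optics$d_b
  n <- light$n_steps
  if (light$adaptive) {
    n2 <- ceiling(2 * a * light$L)
    if (n2 > n) n <- n2
  }
  z <- seq.int(0L, n) * (light$L / n)
  I <- light$I0 * exp(-a * z)
  if (light$n_surfaces == 2L) I <- I + rev(I)
  w <- c(1, rep.int(2, n - 1L), 1)
  k <- sum(w * (I / (I + growth_response$ks + I^2 / growth_response$ki)))
  h <- sum(w * (I / (I + h2_response$ks + I^2 / h2_response$ki)))
  c(k, h) / (2 * n)
}
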