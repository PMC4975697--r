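#' Optical properties of the culture
#'
#' Container for the quantities that set the Beer-Lambert extinction of the
#' culture: the cellular absorption cross-section and the bubble-scattering
#' term of the sparged gas phase. Defaults are the laboratory flat-plate
#' values for *Cyanothece* sp. ATCC 51142.
#'
#' @param tau_c Light absorption cross-section of the cells (m^2 g^-1).
#'   Extinction by biomass is `tau_c * X` with `X` in g m^-3.
#' @param alpha_g Gas hold-up fraction of the sparged culture (dimensionless).
#' @param d_b Mean bubble diameter (m). Bubble scattering contributes
#'   `3 * alpha_g / d_b` (m^-1) to the extinction coefficient.
#' @return An object of class `optical_params`.
#' @seealso [attenuation_coefficient()], [local_intensity()]
#' @export
#' @examples
#' optical_params()                      # laboratory defaults
#' optical_params(tau_c = 0.7 * 0.126)   # a low-chlorophyll mutant
optical_params <- function(tau_c = 0.126, alpha_g = 0.0067, d_b = 0.002) {
  stopifnot(
    "tau_c must be a single positive number" = is_pos_scalar(tau_c),
    "alpha_g must be a single positive number" = is_pos_scalar(alpha_g),
    "d_b must be a single positive number" = is_pos_scalar(d_b)
  )
  structure(list(tau_c = tau_c, alpha_g = alpha_g, d_b = d_b),
            class = "optical_params")
}

#' Reactor illumination geometry
#'
#' Describes the flat-plate light field: incident photon flux per illuminated
#' surface, the light path (reactor width), how many faces are illuminated,
#' and the depth quadrature used to average the photoresponse.
#'
#' The base trapezoid count `n_steps = 20` follows the accuracy study that
#' validated 20 intervals for the 0.025 m laboratory plate. With
#' `adaptive = TRUE` (the default) the interval count is refined to
#' `max(n_steps, ceiling(2 * a * L))` so that the quadrature step never
#' exceeds half the attenuation length `1/a`; without this, thick reactors
#' (`L` of 0.1-0.5 m) under-resolve the millimetre-scale photic boundary
#' layer and the depth average acquires spurious, non-monotone quadrature
#' error. At laboratory optical depths the rule leaves the 20-interval
#' quadrature untouched.
#'
#' @param I0 Incident photon flux density on each illuminated surface
#'   (umol m^-2 s^-1); non-negative.
#' @param L Reactor width, i.e. the light path (m); positive.
#' @param n_surfaces Number of illuminated faces, 1 or 2. With two faces the
#'   local field is the superposition of two opposed Beer-Lambert
#'   exponentials, `I0` on each face.
#' @param n_steps Base number of trapezoid intervals (>= 2).
#' @param adaptive Refine the interval count with optical depth (see above).
#' @return An object of class `light_config`.
#' @export
#' @examples
#' light_config(I0 = 92, L = 0.025)            # laboratory plate
#' light_config(I0 = 457, L = 0.2, n_surfaces = 2)
light_config <- function(I0, L, n_surfaces = 1, n_steps = 20, adaptive = TRUE) {
  stopifnot(
    "I0 must be a single non-negative number" = is_nonneg_scalar(I0),
    "L must be a single positive number" = is_pos_scalar(L),
    "n_surfaces must be 1 or 2" =
      length(n_surfaces) == 1 && n_surfaces %in% c(1, 2),
    "n_steps must be an integer >= 2" =
      length(n_steps) == 1 && n_steps >= 2 && n_steps == round(n_steps),
    "adaptive must be TRUE or FALSE" = isTRUE(adaptive) || isFALSE(adaptive)
  )
  structure(list(I0 = I0, L = L, n_surfaces = as.integer(n_surfaces),
                 n_steps = as.integer(n_steps), adaptive = adaptive),
            class = "light_config")
}

#' Aiba photoresponse parameters
#'
#' Saturation and photoinhibition constants of the Aiba light response
#' `I / (I + ks + I^2/ki)`. Growth uses `ks = 165`, `ki = 457`; hydrogen
#' production uses `ks = 140`, `ki = 457` (all umol m^-2 s^-1).
#'
#' @param ks Light saturation constant (umol m^-2 s^-1); positive.
#' @param ki Photoinhibition constant (umol m^-2 s^-1); positive.
#' @return An object of class `photo_response`.
#' @export
photo_response <- function(ks, ki) {
  stopifnot(
    "ks must be a single positive number" = is_pos_scalar(ks),
    "ki must be a single positive number" = is_pos_scalar(ki)
  )
  structure(list(ks = ks, ki = ki), class = "photo_response")
}

#' Photo-autotrophic growth parameters
#'
#' Kinetic constants of the logistic-type autotrophic growth model
#' `dX/dt = kbar(I) * mu_max_a * X - mu_d_a * X^2` under nitrogen and CO2
#' sufficiency. Defaults are the fitted laboratory values.
#'
#' @param mu_max_a Maximum specific growth rate (h^-1).
#' @param mu_d_a Quadratic decay coefficient (L h^-1 g^-1).
#' @param growth_response [photo_response()] of growth.
#' @return An object of class `autotrophic_params`.
#' @export
autotrophic_params <- function(mu_max_a = 0.255, mu_d_a = 0.00227,
                               growth_response = photo_response(165, 457)) {
  stopifnot(
    "mu_max_a must be a single positive number" = is_pos_scalar(mu_max_a),
    "mu_d_a must be a single positive number" = is_pos_scalar(mu_d_a),
    "growth_response must be a photo_response" =
      inherits(growth_response, "photo_response")
  )
  structure(list(mu_max_a = mu_max_a, mu_d_a = mu_d_a,
                 growth_response = growth_response),
            class = "autotrophic_params")
}

#' Photo-heterotrophic growth and hydrogen production parameters
#'
#' Kinetic constants, yields and light responses of the Droop-quota model of
#' growth on glycerol with nitrogenase-catalysed hydrogen production.
#' Defaults are the fitted laboratory values; the growth light response is
#' shared with the autotrophic model (it is independent of cultivation mode).
#'
#' `K_C = 0` is a degenerate Monod constant: glycerol was always in excess in
#' the fitted experiment, so growth is independent of glycerol level. The
#' Monod factor `C/(C + K_C)` is then taken as 1 for `C > 0` and 0 at
#' `C <= 0`.
#'
#' @param mu_max_h Maximum specific heterotrophic growth rate (h^-1).
#' @param mu_d_h Quadratic decay coefficient (L h^-1 g^-1).
#' @param kq Normalized minimum nitrogen quota, in (0, 1]; growth stops as
#'   the quota `q` falls to `kq`.
#' @param K_N Nitrate half-velocity constant (mg L^-1).
#' @param K_C Glycerol half-velocity constant (mmol L^-1).
#' @param Y_NX Nitrate consumption yield (mg g^-1).
#' @param Y_qX Quota replenishment yield (g^-1).
#' @param Y_HX Hydrogen production yield (mL g^-1 h^-1).
#' @param Y_OX Oxygen production yield on nitrate uptake (L g^-1).
#' @param Y_Od Oxygen consumption yield on decay (L g^-2).
#' @param Y_CX Glycerol consumption yield on growth (mmol g^-1).
#' @param Y_C Glycerol maintenance consumption rate (mmol g^-1 h^-1).
#' @param growth_response [photo_response()] of growth (ks = 165, ki = 457).
#' @param h2_response [photo_response()] of hydrogen production
#'   (ks = 140, ki = 457).
#' @return An object of class `heterotrophic_params`.
#' @export
heterotrophic_params <- function(mu_max_h = 0.332, mu_d_h = 0.00716,
                                 kq = 0.165, K_N = 50.0, K_C = 0.0,
                                 Y_NX = 492.7, Y_qX = 0.0317, Y_HX = 14.20,
                                 Y_OX = 81.02, Y_Od = 486.03, Y_CX = 20.454,
                                 Y_C = 0.0301,
                                 growth_response = photo_response(165, 457),
                                 h2_response = photo_response(140, 457)) {
  nonneg <- c(mu_max_h = mu_max_h, mu_d_h = mu_d_h, K_N = K_N, K_C = K_C,
              Y_NX = Y_NX, Y_qX = Y_qX, Y_HX = Y_HX, Y_OX = Y_OX,
              Y_Od = Y_Od, Y_CX = Y_CX, Y_C = Y_C)
  bad <- names(nonneg)[!vapply(nonneg, is_nonneg_scalar, logical(1))]
  if (length(bad))
    stop("parameters must be single non-negative numbers: ",
         paste(bad, collapse = ", "))
  stopifnot(
    "kq must lie in (0, 1]" = is_pos_scalar(kq) && kq <= 1,
    "growth_response must be a photo_response" =
      inherits(growth_response, "photo_response"),
    "h2_response must be a photo_response" =
      inherits(h2_response, "photo_response")
  )
  structure(c(as.list(nonneg),
              list(kq = kq, growth_response = growth_response,
                   h2_response = h2_response)),
            class = "heterotrophic_params")
}

#' Culture state of a heterotrophic batch
#'
#' The six state variables of the photo-heterotrophic model.
#'
#' @param X Biomass concentration (g L^-1).
#' @param N Nitrate concentration (mg L^-1).
#' @param q Normalized nitrogen quota (dimensionless, > 0; dynamics keep
#'   `q >= kq`).
#' @param C Glycerol concentration (mmol L^-1).
#' @param O2 Accumulated oxygen (L L^-1, model units).
#' @param H2 Cumulative hydrogen (mL L^-1).
#' @return A named numeric vector of class `culture_state`.
#' @export
#' @examples
#' culture_state(X = 0.2, N = 500, q = 1, C = 50)        # nutrient-replete
#' stationary_phase_state(X0 = 3.5)                      # H2-producing preset
culture_state <- function(X, N, q, C, O2 = 0, H2 = 0) {
  v <- c(X = X, N = N, q = q, C = C, O2 = O2, H2 = H2)
  stopifnot(
    "all state variables must be single finite numbers" =
      length(v) == 6 && all(is.finite(v)),
    "X, N, C, O2, H2 must be non-negative" =
      all(v[c("X", "N", "C", "O2", "H2")] >= 0),
    "q must be positive" = v[["q"]] > 0
  )
  structure(v, class = c("culture_state", "numeric"))
}

#' @rdname culture_state
#' @param X0 Initial biomass concentration (g L^-1).
#' @param C0 Initial glycerol concentration (mmol L^-1).
#' @param params Heterotrophic parameters supplying the minimum quota `kq`.
#' @details `stationary_phase_state()` is the scale-up preset for hydrogen
#'   productivity prediction: nitrate exhausted (`N = 0`), quota at its
#'   minimum (`q = kq`, no residual growth), anaerobic (`O2 = 0`), glycerol
#'   ample. Both nitrogenase switches are then fully open and hydrogen is
#'   produced from the start of the batch.
#' @export
stationary_phase_state <- function(X0 = 3.5, C0 = 50,
                                   params = heterotrophic_params()) {
  culture_state(X = X0, N = 0, q = params$kq, C = C0, O2 = 0, H2 = 0)
}

# ---- scalar validation helpers ------------------------------------------

is_pos_scalar <- function(x) is.numeric(x) && length(x) == 1 &&
  is.finite(x) && x > 0

is_nonneg_scalar <- function(x) is.numeric(x) && length(x) == 1 &&
  is.finite(x) && x >= 0

#' @export
print.optical_params <- function(x, ...) {
  cat("Culture optics: tau_c =", x$tau_c, "m^2/g, alpha_g =", x$alpha_g,
      ", d_b =", x$d_b, "m\n")
  cat("  extinction at X = 1 g/L:",
      format(x$tau_c * 1000 + 3 * x$alpha_g / x$d_b), "m^-1\n")
  invisible(x)
}

#' @export
print.light_config <- function(x, ...) {
  cat("Flat-plate light field: I0 =", x$I0, "umol/m^2/s on", x$n_surfaces,
      "surface(s), L =", x$L, "m\n")
  cat("  trapezoid intervals:", x$n_steps,
      if (x$adaptive) "(refined with optical depth)" else "(fixed)", "\n")
  invisible(x)
}

#' @export
print.photo_response <- function(x, ...) {
  cat("Aiba photoresponse: ks =", x$ks, ", ki =", x$ki,
      "umol/m^2/s (optimum at", format(sqrt(x$ks * x$ki), digits = 4),
      ")\n")
  invisible(x)
}

#' @export
print.autotrophic_params <- function(x, ...) {
  cat("Photo-autotrophic growth: mu_max_a =", x$mu_max_a,
      "/h, mu_d_a =", x$mu_d_a, "L/h/g\n")
  print(x$growth_response)
  invisible(x)
}

#' @export
print.heterotrophic_params <- function(x, ...) {
  cat("Photo-heterotrophic growth / H2 production parameters:\n")
  num <- vapply(x[!vapply(x, is.list, logical(1))], identity, numeric(1))
  print(num)
  cat("growth "); print(x$growth_response)
  cat("H2     "); print(x$h2_response)
  invisible(x)
}
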