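#' Nitrogenase switch functions
#'
#' Smooth switches gating hydrogen production. Nitrogenase is active only
#' when nitrate is low and the culture is anaerobic:
#' `switch_fN(N) = 0.5 * (sqrt((N-100)^2) - (N-100)) / sqrt((N-100)^2 + 0.1)`
#' is exactly 0 for nitrate at or above 100 mg L^-1 and approaches 1 as
#' nitrate is depleted; `switch_fO(O2) = 1 - O2 / sqrt(O2^2 + 0.1)` equals 1
#' in anaerobiosis and falls towards 0 as oxygen accumulates. The smoothing
#' constant 0.1 is kept in model units.
#'
#' @param N Nitrate concentration (mg L^-1); non-negative, vectorized.
#' @param O2 Oxygen (L L^-1, model units); non-negative, vectorized.
#' @return Dimensionless factor(s) in `[0, 1]`.
#' @export
#' @examples
#' switch_fN(c(0, 50, 100, 200))
#' switch_fO(c(0, 0.1, 10))
switch_fN <- function(N) {
  if (any(N < 0)) stop("nitrate concentration N must be non-negative")
  d <- N - 100
  0.5 * (sqrt(d^2) - d) / sqrt(d^2 + 0.1)
}

#' @rdname switch_fN
#' @export
switch_fO <- function(O2) {
  if (any(O2 < 0)) stop("oxygen O2 must be non-negative")
  1 - O2 / sqrt(O2^2 + 0.1)
}

# Degenerate-safe Monod factor in glycerol: with K_C = 0 the factor is 1
# for C > 0 and 0 at C <= 0 (limit behaviour; avoids 0/0).
monod_C <- function(C, K_C) {
  if (C <= 0) 0 else C / (C + K_C)
}

# Core derivative computation shared by all integrators. `y` is the state
# vector (X, N, q, C, O2, H2); returns the named derivative vector.
het_derivs <- function(y, params, optics, light) {
  X <- y[[1L]]; N <- y[[2L]]; q <- y[[3L]]
  C <- y[[4L]]; O2 <- y[[5L]]
  if (q <= 0) stop("nitrogen quota q must be positive (got ", q, ")")
  Xp <- max(X, 0)                 # guard tiny negative solver excursions
  Np <- max(N, 0)
  kh <- kbar_hbar(Xp, optics, light, params$growth_response,
                  params$h2_response)
  mu_eff <- kh[1L] * params$mu_max_h
  mN <- Np / (Np + params$K_N)
  mC <- monod_C(C, params$K_C)
  gq <- (1 - params$kq / q)
  grow <- mu_eff * gq * Xp * mC
  decay <- params$mu_d_h * Xp^2
  fO <- switch_fO(max(O2, 0))
  c(X  = grow - decay,
    N  = -params$Y_NX * mu_eff * mN * Xp,
    q  = params$Y_qX * mu_eff * mN - mu_eff * gq * q * mC,
    C  = if (C > 0) -params$Y_CX * grow - params$Y_C * Xp else 0,
    O2 = params$Y_OX * mu_eff * mN * Xp - params$Y_Od * decay * (1 - fO),
    H2 = params$Y_HX * kh[2L] * Xp * switch_fN(Np) * fO)
}

#' Photo-heterotrophic model right-hand side
#'
#' Time derivatives of the six state variables of the Droop-quota growth and
#' hydrogen production model:
#' \describe{
#'   \item{biomass}{`dX/dt = kbar * mu_max_h * (1 - kq/q) * X * C/(C+K_C) -
#'     mu_d_h * X^2` -- quota-limited, light-limited growth with quadratic
#'     decay;}
#'   \item{nitrate}{`dN/dt = -Y_NX * kbar * mu_max_h * N/(N+K_N) * X`;}
#'   \item{quota}{`dq/dt = Y_qX * kbar * mu_max_h * N/(N+K_N) - kbar *
#'     mu_max_h * (1 - kq/q) * q * C/(C+K_C)` -- replenished by nitrate
#'     uptake, diluted by growth;}
#'   \item{glycerol}{`dC/dt = -Y_CX * (growth) - Y_C * X` -- growth plus
#'     maintenance consumption; all glycerol consumption stops once the
#'     pool is exhausted (`C <= 0`), outside the model's fitted domain;}
#'   \item{oxygen}{`dO2/dt = Y_OX * kbar * mu_max_h * N/(N+K_N) * X -
#'     Y_Od * mu_d_h * X^2 * (1 - fO)` -- produced while nitrate is taken
#'     up, consumed by decaying biomass;}
#'   \item{hydrogen}{`dH2/dt = Y_HX * hbar * X * fN(N) * fO(O2)` -- gated by
#'     both nitrogenase switches.}
#' }
#'
#' @param state A [culture_state()] (or named numeric with the same
#'   elements).
#' @param params A [heterotrophic_params()].
#' @param optics An [optical_params()].
#' @param light A [light_config()].
#' @return Named numeric vector of derivatives (per hour).
#' @export
rhs_heterotrophic <- function(state, params, optics, light) {
  stopifnot(inherits(params, "heterotrophic_params"))
  y <- as_state_vector(state)
  het_derivs(y, params, optics, light)
}

as_state_vector <- function(state) {
  vars <- c("X", "N", "q", "C", "O2", "H2")
  if (!is.numeric(state) || is.null(names(state)) ||
      !all(vars %in% names(state)))
    stop("state must be a culture_state or a named numeric vector with ",
         "elements ", paste(vars, collapse = ", "))
  y <- unclass(state)[vars]
  if (y[["q"]] <= 0) stop("nitrogen quota q must be positive")
  y
}

#' Simulate a photo-heterotrophic batch
#'
#' Integrates the six-state model over a time grid. The default integrator
#' is implicit and stiffness-switching; fixed-step RK4 and Radau
#' orthogonal-collocation steppers are available for cross-checks (see
#' [solver_control()]). States are not clamped: small negative excursions of
#' the order of the absolute tolerance are tolerated and reported via the
#' `"min_state"` attribute, and excursions beyond `1e-6` trigger a warning,
#' since they indicate a misconfigured solver rather than model behaviour.
#'
#' @param state0 Initial [culture_state()].
#' @param times Increasing time grid (h).
#' @param params A [heterotrophic_params()].
#' @param optics An [optical_params()].
#' @param light A [light_config()].
#' @param control A [solver_control()].
#' @return A `cyano_trajectory` data frame with columns
#'   `t, X, N, q, C, O2, H2`.
#' @export
#' @examples
#' tr <- simulate_heterotrophic(
#'   culture_state(X = 0.2, N = 500, q = 1, C = 50),
#'   seq(0, 150, 5), heterotrophic_params(), optical_params(),
#'   light_config(I0 = 92, L = 0.025))
#' tr
simulate_heterotrophic <- function(state0, times, params, optics, light,
                                   control = solver_control()) {
  stopifnot(inherits(params, "heterotrophic_params"))
  y0 <- as_state_vector(state0)
  check_times(times)
  rhs_vec <- function(t, y) het_derivs(y, params, optics, light)
  out <- switch(control$method,
    rk4 = rk4_integrate(y0, times, rhs_vec, control$dt),
    collocation = collocation_integrate(y0, times, rhs_vec, control$n_sub),
    run_desolve(y0, times, function(t, y, p) list(het_derivs(y, params,
                optics, light)), control)[, -1L, drop = FALSE]
  )
  mn <- min(out)
  if (mn < -1e-6)
    warning("state excursion below zero (min = ", signif(mn, 3),
            "); consider tightening solver tolerances")
  traj <- new_trajectory(data.frame(t = times, out))
  attr(traj, "min_state") <- mn
  traj
}

#' Average hydrogen productivity of a batch
#'
#' Cumulative hydrogen at the end of a batch divided by its duration. The
#' default starting state is the stationary-phase preset used for reactor
#' scale-up comparisons: 3.5 g L^-1 of biomass, nitrate exhausted, quota at
#' its minimum, anaerobic, glycerol ample (see [stationary_phase_state()]),
#' so both nitrogenase switches are open from the start.
#'
#' @param state0 Initial [culture_state()]; default the stationary-phase
#'   preset.
#' @param duration Batch duration (h), positive; default 240.
#' @param params A [heterotrophic_params()].
#' @param optics An [optical_params()].
#' @param light A [light_config()].
#' @param control A [solver_control()].
#' @return Average productivity (mL L^-1 h^-1).
#' @export
#' @examples
#' average_h2_productivity(params = heterotrophic_params(),
#'                         optics = optical_params(),
#'                         light = light_config(I0 = 457, L = 0.025))
average_h2_productivity <- function(state0 = NULL, duration = 240,
                                    params, optics, light,
                                    control = solver_control()) {
  stopifnot("duration must be a single positive number" =
              is_pos_scalar(duration))
  if (is.null(state0)) state0 <- stationary_phase_state(params = params)
  traj <- simulate_heterotrophic(state0, c(0, duration), params, optics,
                                 light, control)
  traj$H2[nrow(traj)] / duration
}
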