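#' Photo-autotrophic growth rate
#'
#' Right-hand side of the autotrophic batch model
#' `dX/dt = kbar(I; X) * mu_max_a * X - mu_d_a * X^2`: light-limited
#' logistic-type growth with a quadratic decay term. The depth-averaged
#' light response couples the rate to the biomass concentration through
#' self-shading.
#'
#' @param X Biomass concentration (g L^-1), single non-negative value.
#' @param params An [autotrophic_params()].
#' @param optics An [optical_params()].
#' @param light A [light_config()].
#' @return `dX/dt` (g L^-1 h^-1).
#' @export
rhs_autotrophic <- function(X, params, optics, light) {
  stopifnot(inherits(params, "autotrophic_params"))
  if (length(X) != 1 || !is.finite(X) || X < 0)
    stop("X must be a single non-negative number")
  kb <- depth_averaged_response(X, optics, light, params$growth_response)
  kb * params$mu_max_a * X - params$mu_d_a * X^2
}

#' Simulate an autotrophic batch
#'
#' Integrates the autotrophic growth model over a time grid with a
#' stiff-capable solver.
#'
#' @param X0 Initial biomass concentration (g L^-1), positive.
#' @param times Increasing time grid (h).
#' @param params An [autotrophic_params()].
#' @param optics An [optical_params()].
#' @param light A [light_config()].
#' @param control A [solver_control()].
#' @return A `cyano_trajectory` data frame with columns `t` and `X`.
#' @export
#' @examples
#' tr <- simulate_autotrophic(0.1, seq(0, 400, 10), autotrophic_params(),
#'                            optical_params(), light_config(457, 0.025))
#' tail(tr, 3)   # approaches the maximum sustainable concentration
simulate_autotrophic <- function(X0, times, params, optics, light,
                                 control = solver_control()) {
  stopifnot("X0 must be a single positive number" = is_pos_scalar(X0))
  check_times(times)
  rhs <- function(t, y, p) {
    X <- max(y[[1L]], 0)
    kb <- kbar_hbar(X, optics, light, params$growth_response,
                    params$growth_response)[1L]
    list(kb * params$mu_max_a * X - params$mu_d_a * X^2)
  }
  out <- run_desolve(c(X = X0), times, rhs, control)
  new_trajectory(data.frame(t = out[, 1L], X = out[, "X"]))
}

#' Maximum sustainable biomass concentration
#'
#' The plateau (maximum) biomass concentration of an autotrophic batch is the
#' non-trivial equilibrium of the growth model, where depth-averaged growth
#' balances decay: the positive root of
#' `kbar(I; X) * mu_max_a = mu_d_a * X`. Because `kbar` is strictly
#' decreasing in `X` (self-shading) the root is unique and is found by
#' bracketed root-finding.
#'
#' @param params An [autotrophic_params()].
#' @param optics An [optical_params()].
#' @param light A [light_config()].
#' @param lower,upper Root bracket (g L^-1); the defaults span all
#'   physically plausible densities.
#' @param tol Relative tolerance on the root.
#' @return Cmax (g L^-1).
#' @export
#' @examples
#' steady_state_cmax(autotrophic_params(), optical_params(),
#'                   light_config(I0 = 457, L = 0.025))
steady_state_cmax <- function(params, optics, light,
                              lower = 1e-3, upper = 1e3, tol = 1e-6) {
  stopifnot(inherits(params, "autotrophic_params"))
  g <- function(X)
    depth_averaged_response(X, optics, light, params$growth_response) *
      params$mu_max_a - params$mu_d_a * X
  g_lo <- g(lower); g_hi <- g(upper)
  if (sign(g_lo) == sign(g_hi))
    stop("no sign change of the growth-decay balance in [", lower, ", ",
         upper, "] g/L (g(lower) = ", signif(g_lo, 4), ", g(upper) = ",
         signif(g_hi, 4), "); widen the bracket or check the light field")
  stats::uniroot(g, c(lower, upper), f.lower = g_lo, f.upper = g_hi,
                 tol = tol * max(1, lower))$root
}
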