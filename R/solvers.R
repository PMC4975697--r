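#' Integrator settings
#'
#' Controls the numerical integration of the batch models. The system is
#' stiff (the oxygen balance relaxes on a much faster scale than growth), so
#' the default is an implicit, stiffness-switching solver at tight
#' tolerances. A fixed-step classical Runge-Kutta method (`"rk4"`) and a
#' 3-stage Radau IIA orthogonal-collocation stepper (`"collocation"`) are
#' provided as cross-checking integrators; `"rk4"` is intended as a
#' reference oracle, not for production runs.
#'
#' @param method One of `"lsoda"`, `"radau"` (implicit, via \pkg{deSolve}),
#'   `"rk4"` (fixed step), `"collocation"` (fixed elements, Radau IIA
#'   stages solved by Newton iteration).
#' @param rtol,atol Relative/absolute tolerances of the implicit solvers.
#' @param dt Step size (h) of the `"rk4"` method.
#' @param n_sub Number of collocation elements per interval of the output
#'   time grid for `"collocation"`.
#' @return An object of class `solver_control`.
#' @export
solver_control <- function(method = c("lsoda", "radau", "rk4", "collocation"),
                           rtol = 1e-8, atol = 1e-10, dt = 1e-3, n_sub = 8L) {
  method <- match.arg(method)
  stopifnot(is_pos_scalar(rtol), is_pos_scalar(atol), is_pos_scalar(dt),
            is_pos_scalar(n_sub))
  structure(list(method = method, rtol = rtol, atol = atol, dt = dt,
                 n_sub = as.integer(n_sub)),
            class = "solver_control")
}

check_times <- function(times) {
  if (length(times) < 2 || any(!is.finite(times)) || any(diff(times) <= 0))
    stop("times must be a strictly increasing numeric grid of length >= 2")
  invisible(times)
}

new_trajectory <- function(df) {
  rownames(df) <- NULL
  class(df) <- c("cyano_trajectory", "data.frame")
  df
}

#' @export
print.cyano_trajectory <- function(x, ...) {
  cat("Batch trajectory:", nrow(x), "time points over [",
      x$t[1], ",", x$t[nrow(x)], "] h; variables:",
      paste(setdiff(names(x), "t"), collapse = ", "), "\n")
  print.data.frame(utils::head(as.data.frame(x), 4))
  if (nrow(x) > 4) cat("...", nrow(x) - 4, "more rows\n")
  invisible(x)
}

# deSolve wrapper with failure diagnostics. rhs has the deSolve signature
# function(t, y, parms) -> list(dy).
run_desolve <- function(y0, times, rhs, control) {
  out <- try(deSolve::ode(y = y0, times = times, func = rhs, parms = NULL,
                          method = control$method, rtol = control$rtol,
                          atol = control$atol, maxsteps = 20000),
             silent = TRUE)
  if (inherits(out, "try-error"))
    stop("ODE integration failed (method = ", control$method, "): ",
         attr(out, "condition")$message)
  if (nrow(out) < length(times))
    stop("ODE integration stopped early at t = ", out[nrow(out), 1],
         " h (method = ", control$method, ", rtol = ", control$rtol,
         "); diagnostics: ", paste(utils::capture.output(
           deSolve::diagnostics(out)), collapse = " "))
  out
}

# Classical fixed-step RK4 on a uniform internal step, reporting at `times`.
# Reference/oracle integrator: accurate but slow and not stiffness-aware.
# rhs_vec(t, y) -> numeric dy.
rk4_integrate <- function(y0, times, rhs_vec, dt) {
  nv <- length(y0)
  out <- matrix(NA_real_, nrow = length(times), ncol = nv,
                dimnames = list(NULL, names(y0)))
  y <- y0
  t <- times[1L]
  out[1L, ] <- y
  for (i in seq_along(times)[-1L]) {
    tend <- times[i]
    nstep <- max(1L, ceiling((tend - t) / dt - 1e-9))
    h <- (tend - t) / nstep
    for (s in seq_len(nstep)) {
      k1 <- rhs_vec(t, y)
      k2 <- rhs_vec(t + h / 2, y + (h / 2) * k1)
      k3 <- rhs_vec(t + h / 2, y + (h / 2) * k2)
      k4 <- rhs_vec(t + h, y + h * k3)
      y <- y + (h / 6) * (k1 + 2 * k2 + 2 * k3 + k4)
      t <- t + h
    }
    t <- tend
    out[i, ] <- y
  }
  out
}

# ---- Radau IIA orthogonal collocation ------------------------------------
#
# Three-stage Radau IIA: collocation on the right-hand Radau points
# c = ((4 - sqrt(6))/10, (4 + sqrt(6))/10, 1). Within each element the state
# is the degree-3 collocation polynomial; the stage (collocation) equations
# Y_i = y0 + h * sum_j A_ij f(Y_j) are equality constraints solved exactly
# by a damped Newton iteration with a numerically differenced Jacobian.

radau_tableau <- function() {
  s6 <- sqrt(6)
  A <- matrix(c(
    (88 - 7 * s6) / 360,  (296 - 169 * s6) / 1800, (-2 + 3 * s6) / 225,
    (296 + 169 * s6) / 1800, (88 + 7 * s6) / 360,  (-2 - 3 * s6) / 225,
    (16 - s6) / 36,        (16 + s6) / 36,         1 / 9
  ), nrow = 3, byrow = TRUE)
  list(A = A, b = A[3, ], c = c((4 - s6) / 10, (4 + s6) / 10, 1))
}

num_jacobian <- function(f, t, y) {
  nv <- length(y)
  J <- matrix(0, nv, nv)
  f0 <- f(t, y)
  for (j in seq_len(nv)) {
    dy <- max(1e-7, 1e-7 * abs(y[j]))
    yp <- y
    yp[j] <- yp[j] + dy
    J[, j] <- (f(t, yp) - f0) / dy
  }
  J
}

# One collocation element [t, t+h]. Solves the stage equations by exact
# (per-stage Jacobian) damped Newton; returns the stage matrix (3 x nv) --
# the element end state is the third (Radau) stage.
radau_step <- function(rhs_vec, t, y, h, tab, tol = 1e-12, max_iter = 40L) {
  nv <- length(y)
  Y0 <- matrix(rep(y, each = 3), nrow = 3)
  Y <- Y0                                      # stage states, init at y
  F <- matrix(0, 3, nv)
  resid <- function(Y) {
    for (i in 1:3) F[i, ] <<- rhs_vec(t + tab$c[i] * h, Y[i, ])
    Y - Y0 - h * (tab$A %*% F)
  }
  G <- resid(Y)
  gnorm <- max(abs(G))
  for (it in seq_len(max_iter)) {
    if (gnorm < tol * max(1, max(abs(Y)))) return(Y)
    # exact Newton matrix: block (i, j) = delta_ij I - h A_ij J(Y_j)
    M <- diag(3 * nv)
    for (j in 1:3) {
      Jj <- num_jacobian(rhs_vec, t + tab$c[j] * h, Y[j, ])
      for (i in 1:3) {
        ri <- (i - 1) * nv + seq_len(nv)
        cj <- (j - 1) * nv + seq_len(nv)
        M[ri, cj] <- M[ri, cj] - h * tab$A[i, j] * Jj
      }
    }
    dY <- tryCatch(solve(M, as.vector(t(G))), error = function(e)
      stop("collocation Newton matrix is singular at t = ", t, ": ",
           conditionMessage(e)))
    dY <- matrix(dY, nrow = 3, byrow = TRUE)
    lambda <- 1
    repeat {                                   # damped update
      Yn <- Y - lambda * dY
      Gn <- resid(Yn)
      gn <- max(abs(Gn))
      if (gn < gnorm || lambda < 1e-4) break
      lambda <- lambda / 2
    }
    Y <- Yn; G <- Gn; gnorm <- gn
  }
  if (gnorm >= tol * max(1, max(abs(Y))) * 100)
    warning("collocation Newton iteration did not fully converge at t = ",
            t, " (residual ", signif(gnorm, 3), ")")
  Y
}

collocation_integrate <- function(y0, times, rhs_vec, n_sub) {
  tab <- radau_tableau()
  out <- matrix(NA_real_, nrow = length(times), ncol = length(y0),
                dimnames = list(NULL, names(y0)))
  y <- y0
  out[1L, ] <- y
  for (i in seq_along(times)[-1L]) {
    h <- (times[i] - times[i - 1L]) / n_sub
    t <- times[i - 1L]
    for (s in seq_len(n_sub)) {
      Y <- radau_step(rhs_vec, t, y, h, tab)
      y <- Y[3L, ]                      # Radau IIA: last stage is t + h
      t <- t + h
    }
    out[i, ] <- y
  }
  out
}
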