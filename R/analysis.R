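#' Normalized local sensitivity of model outputs
#'
#' Normalized sensitivity `S = (dy/dx) * (x/y)` of an output `y` with
#' respect to a parameter `x`, evaluated along a batch trajectory by central
#' finite differences on a relative perturbation:
#' `S(t) = (y(x*(1+d), t) - y(x*(1-d), t)) / (2 * d * y(x, t))`.
#' A positive value means increasing the parameter increases the output.
#' `S` is undefined where the output vanishes; values at
#' `|y| < floor` are reported as `NA`.
#'
#' Finite differencing of trajectories demands integration error well below
#' the perturbation response, so the default solver tolerances here are
#' tighter than for plain simulation.
#'
#' @param output Character vector of output names (state variables).
#' @param param Single parameter name. For the heterotrophic model any free
#'   name accepted by [estimation_spec()]; for the autotrophic model one of
#'   `mu_max_a`, `mu_d_a`, `ks`, `ki`.
#' @param perturbation Relative perturbation `d` (> 0), default 0.01 (1%).
#' @param times Time grid (h).
#' @param model `"heterotrophic"` or `"autotrophic"`.
#' @param params A [heterotrophic_params()] or [autotrophic_params()]
#'   matching `model`.
#' @param state0 Initial [culture_state()] (heterotrophic) or initial
#'   biomass X0 (autotrophic).
#' @param optics An [optical_params()].
#' @param light A [light_config()].
#' @param control A [solver_control()].
#' @param floor Output magnitude below which `S` is reported `NA`
#'   (default `1e-6`, in the output's units).
#' @return A long-format data frame of class `sensitivity_result` with
#'   columns `t`, `output`, `parameter`, `S`. If the output is identically
#'   below `floor` over the whole window, the result is flagged via the
#'   `"undefined_outputs"` attribute (never NaN-propagated).
#' @export
#' @examples
#' s <- normalized_sensitivity("H2", "Y_HX", times = seq(0, 150, 10),
#'                             params = heterotrophic_params(),
#'                             state0 = culture_state(0.2, 500, 1, 50),
#'                             optics = optical_params(),
#'                             light = light_config(92, 0.025))
#' range(s$S, na.rm = TRUE)   # identically 1 where hydrogen is present
normalized_sensitivity <- function(output, param, perturbation = 0.01,
                                   times = seq(0, 150, by = 1),
                                   model = c("heterotrophic", "autotrophic"),
                                   params, state0, optics, light,
                                   control = solver_control(rtol = 1e-10,
                                                            atol = 1e-12),
                                   floor = 1e-6) {
  model <- match.arg(model)
  stopifnot("perturbation must be a single positive number" =
              is_pos_scalar(perturbation))
  check_times(times)

  run <- function(par) {
    if (model == "heterotrophic")
      simulate_heterotrophic(state0, times, par, optics, light, control)
    else
      simulate_autotrophic(state0, times, par, optics, light, control)
  }
  perturb <- function(fac) {
    if (model == "heterotrophic") {
      base <- get_het_value(params, param)
      apply_free(stats::setNames(base * fac, param), params)
    } else {
      perturb_auto(params, param, fac)
    }
  }
  y0 <- run(params)
  missing_out <- setdiff(output, names(y0))
  if (length(missing_out))
    stop("unknown output(s): ", paste(missing_out, collapse = ", "))
  yp <- run(perturb(1 + perturbation))
  ym <- run(perturb(1 - perturbation))

  res <- do.call(rbind, lapply(output, function(v) {
    base <- y0[[v]]
    S <- (yp[[v]] - ym[[v]]) / (2 * perturbation * base)
    S[abs(base) < floor] <- NA_real_
    data.frame(t = times, output = v, parameter = param, S = S)
  }))
  undef <- output[vapply(output, function(v) all(is.na(
    res$S[res$output == v])), logical(1))]
  rownames(res) <- NULL
  class(res) <- c("sensitivity_result", "data.frame")
  attr(res, "undefined_outputs") <- undef
  attr(res, "floor") <- floor
  res
}

get_het_value <- function(params, name) {
  switch(name,
         ks = params$growth_response$ks,
         ki = params$growth_response$ki,
         ks_H2 = params$h2_response$ks,
         ki_H2 = params$h2_response$ki,
         {
           if (is.null(params[[name]]) || is.list(params[[name]]))
             stop("unknown parameter: ", name)
           params[[name]]
         })
}

perturb_auto <- function(params, name, fac) {
  switch(name,
         mu_max_a = { params$mu_max_a <- params$mu_max_a * fac; params },
         mu_d_a = { params$mu_d_a <- params$mu_d_a * fac; params },
         ks = { params$growth_response$ks <- params$growth_response$ks * fac
                params },
         ki = { params$growth_response$ki <- params$growth_response$ki * fac
                params },
         stop("unknown autotrophic parameter: ", name))
}

#' Flat-plate reactor design point
#'
#' A design triplet: incident intensity per illuminated surface, number of
#' illuminated surfaces, reactor width. Printed keys use the `"I0-n-d"`
#' convention (e.g. `"457-1-0.025"`).
#'
#' @param I0 Incident intensity per surface (umol m^-2 s^-1).
#' @param n_surfaces 1 or 2.
#' @param d Reactor width (m).
#' @return An object of class `reactor_spec`.
#' @export
reactor_spec <- function(I0, n_surfaces, d) {
  lc <- light_config(I0 = I0, L = d, n_surfaces = n_surfaces)  # validates
  structure(list(I0 = I0, n_surfaces = lc$n_surfaces, d = d),
            class = "reactor_spec")
}

#' @export
print.reactor_spec <- function(x, ...) {
  cat("Reactor design ", reactor_key(x), " (I0 per surface - surfaces -",
      " width in m)\n", sep = "")
  invisible(x)
}

reactor_key <- function(spec)
  paste(spec$I0, spec$n_surfaces, spec$d, sep = "-")

#' Reactor scale-up sweep
#'
#' Evaluates a performance metric over a list of reactor design points:
#' `mode = "cmax"` predicts the maximum sustainable biomass concentration of
#' photo-autotrophic cultivation ([steady_state_cmax()]);
#' `mode = "h2"` predicts the average hydrogen productivity of a
#' photo-heterotrophic batch started from the stationary-phase preset
#' (default 3.5 g L^-1 over 240 h, [average_h2_productivity()]).
#' A failure at one design point is isolated (its value is `NA` with a
#' message) and the sweep continues.
#'
#' @param specs List of [reactor_spec()] objects (a single `reactor_spec`
#'   is accepted).
#' @param mode `"cmax"` or `"h2"`.
#' @param auto_params An [autotrophic_params()] (for `"cmax"`).
#' @param het_params A [heterotrophic_params()] (for `"h2"`).
#' @param optics An [optical_params()].
#' @param state0 Initial state for `"h2"`; default the stationary-phase
#'   preset.
#' @param duration Batch duration (h) for `"h2"`.
#' @param control A [solver_control()] for `"h2"`.
#' @return Data frame with columns `key`, `I0`, `n_surfaces`, `d`, `metric`,
#'   `value`.
#' @export
#' @examples
#' sw <- scaleup_sweep(list(reactor_spec(457, 1, 0.025),
#'                          reactor_spec(457, 1, 0.10)), mode = "cmax")
#' sw
scaleup_sweep <- function(specs, mode = c("cmax", "h2"),
                          auto_params = autotrophic_params(),
                          het_params = heterotrophic_params(),
                          optics = optical_params(),
                          state0 = NULL, duration = 240,
                          control = solver_control()) {
  mode <- match.arg(mode)
  if (inherits(specs, "reactor_spec")) specs <- list(specs)
  stopifnot(all(vapply(specs, inherits, logical(1), "reactor_spec")))
  rows <- lapply(specs, function(sp) {
    lc <- light_config(I0 = sp$I0, L = sp$d, n_surfaces = sp$n_surfaces)
    value <- tryCatch({
      if (mode == "cmax")
        steady_state_cmax(auto_params, optics, lc)
      else
        average_h2_productivity(state0 = state0, duration = duration,
                                params = het_params, optics = optics,
                                light = lc, control = control)
    }, error = function(e) {
      message("sweep point ", reactor_key(sp), " failed: ",
              conditionMessage(e))
      NA_real_
    })
    data.frame(key = reactor_key(sp), I0 = sp$I0,
               n_surfaces = sp$n_surfaces, d = sp$d, metric = mode,
               value = value)
  })
  do.call(rbind, rows)
}

#' Low-chlorophyll mutant scenario
#'
#' A hypothetical mutant with the functional absorption cross-section of its
#' photosystem units reduced by a fraction `r`. Because the Aiba constants
#' scale inversely with the cross-section, `ks` and `ki` (and the hydrogen
#' pair) increase by `1/(1-r)`; the cellular extinction cross-section
#' `tau_c`, proportional to the chlorophyll mass fraction, decreases by
#' `(1-r)`. All other kinetic parameters are unchanged. The default 30%
#' reduction mirrors the reduction reported for low-chlorophyll
#' *Dunaliella* isolates.
#'
#' @param cross_section_reduction Fraction `r` in `[0, 1)`; `r = 0` is the
#'   identity transform.
#' @return An object of class `mutant_scenario`.
#' @export
mutant_scenario <- function(cross_section_reduction = 0.30) {
  r <- cross_section_reduction
  if (!is.numeric(r) || length(r) != 1 || !is.finite(r) || r < 0 || r >= 1)
    stop("cross_section_reduction must be a single number in [0, 1)")
  structure(list(cross_section_reduction = r), class = "mutant_scenario")
}

#' Apply the low-chlorophyll mutant transform
#'
#' Rescales the light-response constants and the optical cross-section for a
#' [mutant_scenario()]; see that help page for the scalings. Works on
#' [autotrophic_params()] or [heterotrophic_params()] together with the
#' culture [optical_params()].
#'
#' @param params An [autotrophic_params()] or [heterotrophic_params()].
#' @param optics An [optical_params()].
#' @param scenario A [mutant_scenario()].
#' @return List with transformed `params` and `optics`.
#' @export
#' @examples
#' wt <- mutant_transform(autotrophic_params(), optical_params(),
#'                        mutant_scenario(0.3))
#' wt$params$growth_response   # ks 165 -> 235.7, ki 457 -> 652.9
#' wt$optics$tau_c             # 0.126 -> 0.0882
mutant_transform <- function(params, optics, scenario = mutant_scenario()) {
  stopifnot(inherits(scenario, "mutant_scenario"),
            inherits(optics, "optical_params"),
            inherits(params, "autotrophic_params") ||
              inherits(params, "heterotrophic_params"))
  keep <- 1 - scenario$cross_section_reduction
  params$growth_response$ks <- params$growth_response$ks / keep
  params$growth_response$ki <- params$growth_response$ki / keep
  if (inherits(params, "heterotrophic_params")) {
    params$h2_response$ks <- params$h2_response$ks / keep
    params$h2_response$ki <- params$h2_response$ki / keep
  }
  optics$tau_c <- optics$tau_c * keep
  list(params = params, optics = optics)
}
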