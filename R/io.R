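# Configuration schema: every parameter carries a canonical unit; config
# leaves may be a bare number (canonical unit assumed) or a map
# {value: v, unit: "..."} whose unit must match the canonical string.

config_schema <- function() {
  num <- function(default, unit, min = -Inf, max = Inf)
    list(kind = "num", default = default, unit = unit, min = min, max = max)
  int <- function(default, unit, min, max = Inf)
    list(kind = "int", default = default, unit = unit, min = min, max = max)
  flag <- function(default)
    list(kind = "flag", default = default, unit = "1")
  choice <- function(default, choices)
    list(kind = "choice", default = default, unit = "1", choices = choices)
  uE <- "umol m^-2 s^-1"
  list(
    model = choice("heterotrophic", c("heterotrophic", "autotrophic")),
    seed = int(1L, "1", min = 0),
    optics = list(
      tau_c = num(0.126, "m^2 g^-1", min = 1e-12),
      alpha_g = num(0.0067, "1", min = 1e-12),
      d_b = num(0.002, "m", min = 1e-12)
    ),
    light = list(
      I0 = num(92, uE, min = 0),
      L = num(0.025, "m", min = 1e-12),
      n_surfaces = int(1L, "1", min = 1, max = 2),
      n_steps = int(20L, "1", min = 2),
      adaptive = flag(TRUE)
    ),
    autotrophic = list(
      mu_max_a = num(0.255, "h^-1", min = 1e-12),
      mu_d_a = num(0.00227, "L h^-1 g^-1", min = 1e-12),
      ks = num(165, uE, min = 1e-12),
      ki = num(457, uE, min = 1e-12)
    ),
    heterotrophic = list(
      mu_max_h = num(0.332, "h^-1", min = 0),
      mu_d_h = num(0.00716, "L h^-1 g^-1", min = 0),
      kq = num(0.165, "1", min = 1e-12, max = 1),
      K_N = num(50.0, "mg L^-1", min = 0),
      K_C = num(0.0, "mmol L^-1", min = 0),
      Y_NX = num(492.7, "mg g^-1", min = 0),
      Y_qX = num(0.0317, "g^-1", min = 0),
      Y_HX = num(14.20, "mL g^-1 h^-1", min = 0),
      Y_OX = num(81.02, "L g^-1", min = 0),
      Y_Od = num(486.03, "L g^-2", min = 0),
      Y_CX = num(20.454, "mmol g^-1", min = 0),
      Y_C = num(0.0301, "mmol g^-1 h^-1", min = 0),
      ks = num(165, uE, min = 1e-12),
      ki = num(457, uE, min = 1e-12),
      ks_H2 = num(140, uE, min = 1e-12),
      ki_H2 = num(457, uE, min = 1e-12)
    ),
    initial_state = list(
      X = num(0.2, "g L^-1", min = 0),
      N = num(500, "mg L^-1", min = 0),
      q = num(1.0, "1", min = 1e-12),
      C = num(50, "mmol L^-1", min = 0),
      O2 = num(0, "L L^-1", min = 0),
      H2 = num(0, "mL L^-1", min = 0)
    ),
    times = list(
      from = num(0, "h"),
      to = num(150, "h"),
      by = num(1, "h", min = 1e-9)
    ),
    solver = list(
      method = choice("lsoda", c("lsoda", "radau", "rk4", "collocation")),
      rtol = num(1e-8, "1", min = 1e-15),
      atol = num(1e-10, "1", min = 1e-18),
      dt = num(1e-3, "h", min = 1e-9),
      n_sub = int(4L, "1", min = 1)
    )
  )
}

# YAML 1.1 resolves a bare `N` key to boolean false; restore the nitrate key
# (the only schema key caught by implicit boolean typing).
fix_yaml_keys <- function(x) {
  if (!is.list(x)) return(x)
  nm <- names(x)
  if (!is.null(nm)) names(x) <- ifelse(nm == "FALSE", "N", nm)
  lapply(x, fix_yaml_keys)
}

validate_node <- function(value, schema, path) {
  if (!("kind" %in% names(schema))) {        # interior node
    if (is.null(value)) value <- list()
    if (!is.list(value))
      stop("config key '", path, "' must be a mapping", call. = FALSE)
    unknown <- setdiff(names(value), names(schema))
    if (length(unknown))
      stop("unknown config key(s): ",
           paste(paste0(path, ".", unknown), collapse = ", "), call. = FALSE)
    return(stats::setNames(lapply(names(schema), function(k)
      validate_node(value[[k]], schema[[k]], paste0(path, ".", k))),
      names(schema)))
  }
  if (is.null(value)) return(schema$default)
  # leaf: either bare value or {value:, unit:}
  if (is.list(value)) {
    extra <- setdiff(names(value), c("value", "unit"))
    if (length(extra) || !"value" %in% names(value))
      stop("config key '", path,
           "' must be a value or a {value, unit} mapping", call. = FALSE)
    if (!is.null(value$unit) && !identical(value$unit, schema$unit))
      stop("config key '", path, "' has unit '", value$unit,
           "' but expects '", schema$unit, "'", call. = FALSE)
    value <- value$value
  }
  switch(schema$kind,
    flag = {
      if (!(isTRUE(value) || isFALSE(value)))
        stop("config key '", path, "' must be true or false", call. = FALSE)
      value
    },
    choice = {
      if (!is.character(value) || length(value) != 1 ||
          !value %in% schema$choices)
        stop("config key '", path, "' must be one of: ",
             paste(schema$choices, collapse = ", "), call. = FALSE)
      value
    },
    {
      if (!is.numeric(value) || length(value) != 1 || !is.finite(value))
        stop("config key '", path, "' must be a single finite number",
             call. = FALSE)
      if (value < schema$min || value > schema$max)
        stop("config key '", path, "' = ", value, " is out of range [",
             schema$min, ", ", schema$max, "]", call. = FALSE)
      if (schema$kind == "int") {
        if (value != round(value))
          stop("config key '", path, "' must be an integer", call. = FALSE)
        as.integer(value)
      } else as.numeric(value)
    })
}

#' Load, validate and resolve a run configuration
#'
#' Reads a YAML run configuration, applies defaults for every omitted block,
#' rejects unknown keys, and checks units and ranges. Each parameter may be
#' given as a bare number (canonical unit assumed) or as
#' `{value: v, unit: "..."}`, in which case the unit string must match the
#' canonical unit of that key (see the annotated example installed at
#' `system.file("extdata", "config_example.yaml", package = "cyanoH2")`).
#' An empty (or missing `path = NULL`) configuration resolves to the full
#' laboratory defaults.
#'
#' @param path Path to a YAML file, or `NULL` for pure defaults.
#' @return A validated nested list of class `run_config`.
#' @export
load_config <- function(path = NULL) {
  raw <- if (is.null(path)) list() else {
    if (!file.exists(path)) stop("config file not found: ", path)
    x <- yaml::read_yaml(path)
    if (is.null(x)) list() else fix_yaml_keys(x)
  }
  if (!is.list(raw)) stop("config root must be a mapping")
  cfg <- validate_node(raw, config_schema(), "")
  names(cfg) <- names(config_schema())
  # strip the leading "." from error paths by validating with proper root
  class(cfg) <- "run_config"
  cfg
}

#' @rdname load_config
#' @param cfg A `run_config`.
#' @details `save_config()` writes the resolved configuration back to YAML;
#'   a save/load round trip is the identity on resolved configurations.
#' @export
save_config <- function(cfg, path) {
  stopifnot(inherits(cfg, "run_config"))
  yaml::write_yaml(unclass(cfg), path)
  invisible(path)
}

#' @export
print.run_config <- function(x, ...) {
  cat("Run configuration (", x$model, " model):\n", sep = "")
  utils::str(unclass(x), give.attr = FALSE)
  invisible(x)
}

# Materialize parameter objects from a validated config.
config_objects <- function(cfg) {
  stopifnot(inherits(cfg, "run_config"))
  het <- cfg$heterotrophic
  list(
    model = cfg$model,
    seed = cfg$seed,
    optics = optical_params(cfg$optics$tau_c, cfg$optics$alpha_g,
                            cfg$optics$d_b),
    light = light_config(cfg$light$I0, cfg$light$L, cfg$light$n_surfaces,
                         cfg$light$n_steps, cfg$light$adaptive),
    auto_params = autotrophic_params(
      cfg$autotrophic$mu_max_a, cfg$autotrophic$mu_d_a,
      photo_response(cfg$autotrophic$ks, cfg$autotrophic$ki)),
    het_params = heterotrophic_params(
      mu_max_h = het$mu_max_h, mu_d_h = het$mu_d_h, kq = het$kq,
      K_N = het$K_N, K_C = het$K_C, Y_NX = het$Y_NX, Y_qX = het$Y_qX,
      Y_HX = het$Y_HX, Y_OX = het$Y_OX, Y_Od = het$Y_Od, Y_CX = het$Y_CX,
      Y_C = het$Y_C,
      growth_response = photo_response(het$ks, het$ki),
      h2_response = photo_response(het$ks_H2, het$ki_H2)),
    state0 = culture_state(cfg$initial_state$X, cfg$initial_state$N,
                           cfg$initial_state$q, cfg$initial_state$C,
                           cfg$initial_state$O2, cfg$initial_state$H2),
    times = seq(cfg$times$from, cfg$times$to, by = cfg$times$by),
    control = solver_control(cfg$solver$method, cfg$solver$rtol,
                             cfg$solver$atol, cfg$solver$dt,
                             cfg$solver$n_sub)
  )
}

#' Write or read a batch trajectory
#'
#' Trajectories round-trip through headered CSV exactly (full double
#' precision). The units of the columns are `t` h, `X` g/L, `N` mg/L, `q`
#' dimensionless, `C` mmol/L, `O2` L/L, `H2` mL/L.
#'
#' @param traj A `cyano_trajectory` (or data frame with a `t` column).
#' @param path File path.
#' @return `read_trajectory()` returns a `cyano_trajectory`;
#'   `write_trajectory()` returns `path` invisibly.
#' @export
write_trajectory <- function(traj, path) {
  stopifnot(is.data.frame(traj), "t" %in% names(traj))
  df <- as.data.frame(traj)
  df[] <- lapply(df, function(col) sprintf("%.17g", col))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_trajectory
#' @export
read_trajectory <- function(path) {
  df <- utils::read.csv(path, colClasses = "numeric")
  if (!"t" %in% names(df)) stop("trajectory file must have a 't' column")
  new_trajectory(df)
}
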