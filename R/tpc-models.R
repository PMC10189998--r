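#' Physical constants used by the thermal models
#'
#' Boltzmann constant `k` (eV/K), the reference temperature `t_ref` (degC) at
#' which the amplitude parameters are anchored, and the Celsius-to-Kelvin
#' offset. These are fixed constants of the model, not tunable parameters.
#'
#' @format A list with elements `k` (8.617e-5 eV/K), `t_ref` (15 degC) and
#'   `kelvin_offset` (273.15).
#' @export
tpc_constants <- list(
  k = 8.617e-5,
  t_ref = 15,
  kelvin_offset = 273.15
)

# Boltzmann-Arrhenius rise relative to the reference temperature.
boltzmann_factor <- function(E, temp, t_ref = tpc_constants$t_ref) {
  K0 <- tpc_constants$kelvin_offset
  exp(-E / tpc_constants$k * (1 / (temp + K0) - 1 / (t_ref + K0)))
}

tpc_model_names <- c("gaussian", "modified_gaussian", "quadratic", "weibull", "pawar")

tpc_gaussian <- function(params, temp) {
  params[["r_max"]] * exp(-0.5 * ((temp - params[["t_opt"]]) / params[["a"]])^2)
}

tpc_modified_gaussian <- function(params, temp) {
  params[["r_max"]] *
    exp(-0.5 * (abs(temp - params[["t_opt"]]) / params[["a"]])^params[["b"]])
}

tpc_quadratic <- function(params, temp) {
  params[["a"]] + params[["b"]] * temp + params[["c"]] * temp^2
}

# Four-parameter Weibull TPC. Below the support of the non-integer power
# (negative base) the rate is defined as 0 so residuals stay finite for the
# optimizer.
tpc_weibull <- function(params, temp) {
  a <- params[["a"]]
  t_opt <- params[["t_opt"]]
  b <- params[["b"]]
  cc <- params[["c"]]
  q <- ((cc - 1) / cc)
  base <- (temp - t_opt) / b + q^(1 / cc)
  out <- numeric(length(base))
  ok <- base > 0
  out[ok] <- a * q^((1 - cc) / cc) * base[ok]^(cc - 1) * exp(-base[ok]^cc + q)
  out
}

# Modified Sharpe-Schoolfield with an explicit optimum-temperature parameter;
# the curve's maximum falls exactly at t_opt (see the methods vignette).
tpc_pawar <- function(params, temp) {
  E <- params[["E"]]
  E_h <- params[["E_h"]]
  if (E_h <= E) {
    stop("pawar model requires E_h > E (got E_h = ", E_h, ", E = ", E, ")")
  }
  t_opt <- params[["t_opt"]]
  K0 <- tpc_constants$kelvin_offset
  num <- boltzmann_factor(E, temp)
  den <- 1 + (E / (E_h - E)) *
    exp(E_h / tpc_constants$k * (1 / (t_opt + K0) - 1 / (temp + K0)))
  params[["r_ref"]] * num / den
}

#' Evaluate a thermal performance curve model
#'
#' @param name Model name, one of `"gaussian"`, `"modified_gaussian"`,
#'   `"quadratic"`, `"weibull"`, `"pawar"`.
#' @param params Numeric parameter vector in the order given by
#'   [model_spec()]`$param_names` (names are optional and ignored in favour of
#'   position).
#' @param temp Temperature(s) in degC; the function is vectorized over `temp`.
#' @return Rate values (same units as the fitted response, here m/s) of the
#'   same length as `temp`.
#' @examples
#' eval_model("gaussian", c(r_max = 0.05, t_opt = 25, a = 5), 25)
#' eval_model("pawar", c(0.03, 0.37, 3.11, 26.33), seq(8, 32, 2))
#' @export
eval_model <- function(name, params, temp) {
  spec <- model_spec(name)
  if (length(params) != spec$n_params) {
    stop(sprintf("model '%s' expects %d parameters, got %d",
                 name, spec$n_params, length(params)))
  }
  params <- stats::setNames(as.numeric(params), spec$param_names)
  spec$fn(params, temp)
}

#' Model registry entry for a TPC family
#'
#' Returns the parameter names, box bounds and multistart start-value ranges
#' used by the fitting machinery, tuned for movement-speed responses in m/s
#' over temperatures in degC.
#'
#' The pawar family is handled internally in the reparameterisation
#' `E_h = E + exp(theta)` which enforces `E_h > E`; the public interface
#' (parameter names, estimates, standard errors) always uses `E_h` itself.
#'
#' @param name Model name (see [eval_model()]).
#' @return An object of class `tpc_model_spec`: a list with `name`,
#'   `param_names`, `n_params`, `lower`, `upper`, `start_lower`, `start_upper`
#'   (all on the public scale), the evaluation function `fn`, and internal
#'   transform hooks used by the optimizer.
#' @export
model_spec <- function(name) {
  if (length(name) != 1 || !name %in% tpc_model_names) {
    stop("unknown model '", paste(name, collapse = ","),
         "'; valid models: ", paste(tpc_model_names, collapse = ", "))
  }
  spec <- switch(name,
    gaussian = list(
      param_names = c("r_max", "t_opt", "a"),
      lower = c(1e-8, 0, 0.1),
      upper = c(1, 60, 60),
      start_lower = c(1e-3, 10, 1),
      start_upper = c(0.2, 40, 20),
      fn = tpc_gaussian
    ),
    modified_gaussian = list(
      param_names = c("r_max", "t_opt", "a", "b"),
      lower = c(1e-8, 0, 0.1, 0.1),
      upper = c(1, 60, 60, 10),
      start_lower = c(1e-3, 10, 1, 1),
      start_upper = c(0.2, 40, 20, 4),
      fn = tpc_modified_gaussian
    ),
    quadratic = list(
      param_names = c("a", "b", "c"),
      lower = c(-Inf, -Inf, -Inf),
      upper = c(Inf, Inf, Inf),
      start_lower = c(-0.1, -0.01, -0.001),
      start_upper = c(0.1, 0.01, 0.001),
      fn = tpc_quadratic
    ),
    weibull = list(
      param_names = c("a", "t_opt", "b", "c"),
      lower = c(1e-8, 0, 0.5, 1.01),
      upper = c(1, 60, 200, 30),
      start_lower = c(1e-3, 10, 5, 1.5),
      start_upper = c(0.2, 40, 60, 10),
      fn = tpc_weibull
    ),
    pawar = list(
      param_names = c("r_ref", "E", "E_h", "t_opt"),
      lower = c(1e-8, 1e-3, NA, 0),
      upper = c(1, 4, NA, 60),
      start_lower = c(1e-3, 0.05, NA, 10),
      start_upper = c(0.2, 2, NA, 40),
      fn = tpc_pawar
    )
  )
  spec$name <- name
  spec$n_params <- length(spec$param_names)
  if (name == "pawar") {
    spec <- c(spec, pawar_internal_hooks(e_index = 2L, gap_index = 3L))
    spec <- finish_gap_spec(spec)
  } else {
    spec$to_internal <- identity
    spec$from_internal <- identity
    spec$internal_lower <- spec$lower
    spec$internal_upper <- spec$upper
    spec$internal_start_lower <- spec$start_lower
    spec$internal_start_upper <- spec$start_upper
  }
  class(spec) <- "tpc_model_spec"
  spec
}

# Internal reparameterisation shared by the pawar TPC and the combined
# allometric model: position `gap_index` holds E_h publicly and
# theta = log(E_h - E) internally. Start range for the gap spans 0.1-10 eV.
pawar_internal_hooks <- function(e_index, gap_index, lower = NULL, upper = NULL,
                                 start_lower = NULL, start_upper = NULL) {
  to_internal <- function(p) {
    p[gap_index] <- log(p[gap_index] - p[e_index])
    p
  }
  from_internal <- function(p) {
    p[gap_index] <- p[e_index] + exp(p[gap_index])
    p
  }
  hooks <- list(to_internal = to_internal, from_internal = from_internal)
  hooks$gap_index <- gap_index
  hooks
}

# Fill internal bounds/starts for a spec that uses the gap reparameterisation.
finish_gap_spec <- function(spec, gap_start = c(0.1, 10), gap_bounds = c(1e-4, 30)) {
  gi <- spec$gap_index
  spec$internal_lower <- spec$lower
  spec$internal_upper <- spec$upper
  spec$internal_start_lower <- spec$start_lower
  spec$internal_start_upper <- spec$start_upper
  spec$internal_lower[gi] <- log(gap_bounds[1])
  spec$internal_upper[gi] <- log(gap_bounds[2])
  spec$internal_start_lower[gi] <- log(gap_start[1])
  spec$internal_start_upper[gi] <- log(gap_start[2])
  spec
}

#' @export
print.tpc_model_spec <- function(x, ...) {
  cat("TPC model spec:", x$name, "\n")
  tab <- data.frame(
    parameter = x$param_names,
    lower = x$lower, upper = x$upper,
    start_lower = x$start_lower, start_upper = x$start_upper
  )
  print(tab, row.names = FALSE)
  invisible(x)
}

#' List the available TPC model families
#'
#' @return Character vector of registry names usable with [model_spec()],
#'   [eval_model()] and [compare_models()].
#' @export
list_models <- function() tpc_model_names
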