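#' Parameter vector of the combined allometric-thermal speed model
#'
#' The model predicts exploratory speed v (m/s) from body mass M (mg) and
#' temperature T (degC) as a body-mass power law multiplied by a modified
#' Sharpe-Schoolfield thermal response:
#'
#' v = a0 M^b exp(-E/k (1/(T+273.15) - 1/(T_ref+273.15))) /
#'     (1 + (E/(E_h - E)) exp(E_h/k (1/(T_opt+273.15) - 1/(T+273.15))))
#'
#' `a0` is the speed of a 1 mg animal at the reference temperature (15 degC),
#' `b` the allometric exponent, `E` (eV) the activation energy controlling the
#' rise below the optimum, `E_h` (eV) the deactivation energy controlling the
#' collapse above it, and `t_opt` (degC) the temperature at which speed peaks.
#'
#' @param a0 Speed at T_ref for M = 1 mg (m/s, > 0).
#' @param b Allometric exponent (dimensionless).
#' @param E Activation energy (eV, > 0).
#' @param E_h Deactivation energy (eV, must exceed `E`).
#' @param t_opt Optimum temperature (degC).
#' @return A named numeric vector of class `allo_params`.
#' @examples
#' allo_params(a0 = 0.03, b = 0.12, E = 0.37, E_h = 3.11, t_opt = 26.33)
#' @export
allo_params <- function(a0, b, E, E_h, t_opt) {
  if (a0 <= 0) stop("a0 must be > 0")
  if (E <= 0) stop("E must be > 0")
  if (E_h <= E) stop("E_h must exceed E (got E_h = ", E_h, ", E = ", E, ")")
  if (!is.finite(t_opt)) stop("t_opt must be finite")
  structure(c(a0 = a0, b = b, E = E, E_h = E_h, t_opt = t_opt),
            class = "allo_params")
}

#' Evaluate the allometric-thermal speed model
#'
#' @param params An [allo_params()] vector (or any numeric vector ordered
#'   `a0, b, E, E_h, t_opt`).
#' @param mass Body mass in mg (> 0); recycled against `temp`.
#' @param temp Temperature in degC.
#' @return Predicted speeds in m/s.
#' @examples
#' p <- allo_params(0.03, 0.12, 0.37, 3.11, 26.33)
#' eval_allo_tpc(p, mass = 105, temp = seq(8, 32, 4))
#' @export
eval_allo_tpc <- function(params, mass, temp) {
  p <- as.numeric(params)
  if (length(p) != 5) stop("expected 5 parameters (a0, b, E, E_h, t_opt)")
  if (any(mass <= 0)) stop("mass must be > 0 (mg)")
  if (p[4] <= p[3]) stop("E_h must exceed E")
  p[1] * mass^p[2] *
    tpc_pawar(c(r_ref = 1, E = p[3], E_h = p[4], t_opt = p[5]), temp)
}

# Spec object for the 5-parameter combined model; same gap reparameterisation
# as the pawar TPC (E_h = E + exp(theta)).
allo_model_spec <- function() {
  spec <- list(
    name = "allo_pawar",
    param_names = c("a0", "b", "E", "E_h", "t_opt"),
    lower = c(1e-8, -2, 1e-3, NA, 0),
    upper = c(1, 2, 4, NA, 60),
    start_lower = c(1e-4, -0.5, 0.05, NA, 10),
    start_upper = c(0.5, 1, 2, NA, 40),
    fn = NULL
  )
  spec$n_params <- 5L
  spec <- c(spec, pawar_internal_hooks(e_index = 3L, gap_index = 4L))
  spec <- finish_gap_spec(spec)
  class(spec) <- "tpc_model_spec"
  spec
}

allo_predict_fn <- function(par, data) {
  par <- as.numeric(par)
  par[1] * data$mass^par[2] *
    tpc_pawar(c(r_ref = 1, E = par[3], E_h = par[4], t_opt = par[5]), data$temp)
}

#' Fit the allometric-thermal model to per-individual speed records
#'
#' Multistart bounded nonlinear least squares over (a0, b, E, E_h, t_opt),
#' minimising the squared error of observed speeds on the natural (not log)
#' scale. Reuses the same optimisation machinery as [fit_multistart()].
#'
#' @param records Data.frame with columns `mass` (mg), `temperature` (degC)
#'   and `speed` (m/s); extra columns (`individual_id`, `species`,
#'   `habitat_group`) are carried along for [residual_table()]. Rows with
#'   missing speed are dropped.
#' @param n_starts Number of random starts (default 100; the 5-parameter
#'   problem converges reliably from the informative start ranges).
#' @param seed Integer seed for start draws.
#' @return A `tpc_fit` (additionally of class `allo_fit`) with the fitted
#'   records attached.
#' @export
fit_allo_tpc <- function(records, n_starts = 100, seed = 1) {
  req <- c("mass", "temperature", "speed")
  miss <- setdiff(req, names(records))
  if (length(miss)) stop("records lack columns: ", paste(miss, collapse = ", "))
  records <- records[is.finite(records$speed), , drop = FALSE]
  n <- nrow(records)
  if (n < 7) stop("need at least 7 usable records, got ", n)
  if (length(unique(records$mass)) < 2) {
    stop("all records share one body mass; allometric exponent b is unidentifiable")
  }
  if (length(unique(records$temperature)) < 2) {
    stop("all records share one temperature; thermal parameters are unidentifiable")
  }
  if (any(records$mass <= 0)) stop("mass must be > 0 (mg)")
  if (any(records$speed < 0)) stop("speed must be non-negative")

  fit <- ls_multistart(allo_model_spec(), allo_predict_fn,
                       data = list(mass = records$mass, temp = records$temperature),
                       response = records$speed,
                       n_starts = n_starts, seed = seed)
  fit$records <- records
  class(fit) <- c("allo_fit", class(fit))
  fit
}

#' Prediction surface of the allometric-thermal model
#'
#' Evaluates the model on the outer grid of masses and temperatures, the form
#' behind speed-vs-temperature curves at fixed masses and speed-vs-mass curves
#' at fixed temperatures.
#'
#' @param params An [allo_params()] vector.
#' @param masses Body masses in mg (> 0).
#' @param temperatures Temperatures in degC.
#' @return A `prediction_grid`: list with `masses`, `temperatures` and a
#'   `speeds` matrix (rows = masses, columns = temperatures). Use
#'   [as.data.frame()] for a long-format table.
#' @export
predict_grid <- function(params, masses, temperatures) {
  if (any(masses <= 0)) stop("masses must be > 0 (mg)")
  speeds <- outer(masses, temperatures,
                  function(m, t) eval_allo_tpc(params, m, t))
  dimnames(speeds) <- list(mass = format(masses, trim = TRUE),
                           temperature = format(temperatures, trim = TRUE))
  structure(list(masses = masses, temperatures = temperatures, speeds = speeds),
            class = "prediction_grid")
}

#' @export
as.data.frame.prediction_grid <- function(x, ...) {
  data.frame(
    mass = rep(x$masses, times = length(x$temperatures)),
    temperature = rep(x$temperatures, each = length(x$masses)),
    speed = as.vector(x$speeds)
  )
}

#' @export
print.prediction_grid <- function(x, ...) {
  cat(sprintf("Prediction grid: %d masses x %d temperatures, speeds %.4g-%.4g m/s\n",
              length(x$masses), length(x$temperatures),
              min(x$speeds), max(x$speeds)))
  invisible(x)
}

#' Per-record residual table of a fitted allometric-thermal model
#'
#' @param fit An `allo_fit` from [fit_allo_tpc()].
#' @param records Records to evaluate; defaults to the records the model was
#'   fitted to.
#' @return Data.frame with one row per record: any of `individual_id`,
#'   `species`, `habitat_group` present in the records, plus `observed`,
#'   `predicted` and `residual` (m/s).
#' @export
residual_table <- function(fit, records = NULL) {
  if (is.null(records)) records <- fit$records
  pred <- eval_allo_tpc(fit$estimates, records$mass, records$temperature)
  keep <- intersect(c("individual_id", "species", "habitat_group",
                      "mass", "temperature"), names(records))
  out <- records[, keep, drop = FALSE]
  out$observed <- records$speed
  out$predicted <- pred
  out$residual <- records$speed - pred
  rownames(out) <- NULL
  out
}
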