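#' Gaussian-likelihood AIC from a residual sum of squares
#'
#' Uses the convention of R's `AIC()` on `nls` objects, where the error
#' variance counts as a parameter:
#' `AIC = n log(2 pi) + n log(rss / n) + n + 2 (p + 1)`.
#' Absolute AIC values therefore match what `AIC(nls(...))` would report on the
#' same data; AIC differences within a dataset do not depend on the additive
#' `n log(2 pi) + n` constant.
#'
#' @param rss Residual sum of squares (must be > 0).
#' @param n_obs Number of observations.
#' @param n_params Number of mean-function parameters (excluding the error
#'   variance).
#' @return The AIC value.
#' @export
aic_rss <- function(rss, n_obs, n_params) {
  if (rss <= 0) {
    stop("AIC undefined for rss <= 0 (degenerate perfect fit)")
  }
  n_obs * log(2 * pi) + n_obs * log(rss / n_obs) + n_obs + 2 * (n_params + 1)
}

#' @export
AIC.tpc_fit <- function(object, ..., k = 2) {
  aic_rss(object$rss, object$n_obs, object$n_params)
}

# Residual closure with a finite-value guard: parameter combinations that
# evaluate outside a model's support would otherwise feed NaN to the optimizer.
ls_residual_fn <- function(predict_fn, data, response) {
  n <- length(response)
  function(par) {
    pred <- predict_fn(par, data)
    r <- response - pred
    r[!is.finite(r)] <- 1e6
    if (length(r) != n) r <- rep(1e6, n)
    r
  }
}

# Multistart bounded least-squares driver shared by the pure-TPC and the
# combined allometric fits. `predict_fn(par_public, data)` evaluates the mean
# function; optimisation happens on the internal scale defined by the spec's
# transform hooks. Starts are drawn sequentially so the first k starts of a
# longer run coincide with a shorter run under the same seed.
ls_multistart <- function(spec, predict_fn, data, response, n_starts, seed,
                          model_name = spec$name) {
  p <- spec$n_params
  n <- length(response)
  if (n <= p) {
    stop(sprintf("need more observations (%d) than parameters (%d)", n, p))
  }
  resid_internal <- local({
    from_internal <- spec$from_internal
    rf <- ls_residual_fn(predict_fn, data, response)
    function(par) rf(from_internal(par))
  })
  ctrl <- minpack.lm::nls.lm.control(ftol = 1e-12, ptol = 1e-12, maxiter = 500)

  old_seed <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, envir = globalenv()))
  set.seed(seed)

  best <- NULL
  n_converged <- 0L
  for (i in seq_len(n_starts)) {
    start <- spec$internal_start_lower +
      stats::runif(p) * (spec$internal_start_upper - spec$internal_start_lower)
    fit <- tryCatch(
      minpack.lm::nls.lm(par = start, lower = spec$internal_lower,
                         upper = spec$internal_upper, fn = resid_internal,
                         control = ctrl),
      error = function(e) NULL
    )
    if (is.null(fit) || !(fit$info %in% 1:4)) next
    n_converged <- n_converged + 1L
    if (is.null(best) || fit$deviance < best$deviance) best <- fit
  }
  if (is.null(best)) {
    stop("no multistart run converged; widen bounds/start ranges or increase n_starts")
  }
  # polish the winner with undamped Gauss-Newton steps: L-M's stopping rule
  # leaves the last few digits on the table (exact for linear models)
  best <- polish_gauss_newton(resid_internal, best,
                              spec$internal_lower, spec$internal_upper)

  est <- spec$from_internal(best$par)
  names(est) <- spec$param_names
  rss <- best$deviance
  se <- fit_std_errors(predict_fn, data, est, rss, n)

  structure(list(
    model_name = model_name,
    estimates = est,
    std_errors = se,
    rss = rss,
    n_obs = n,
    n_params = p,
    aic = if (rss > 0) aic_rss(rss, n, p) else -Inf,
    converged = TRUE,
    n_starts = n_starts,
    n_starts_converged = n_converged,
    seed = seed,
    spec = spec,
    predict_fn = predict_fn,
    data = data,
    response = response,
    fitted = predict_fn(est, data)
  ), class = "tpc_fit")
}

# A few full Gauss-Newton steps from a converged L-M solution, clamped to the
# bounds and accepted only while the deviance improves. Skipped silently when
# J'J is (near-)singular, e.g. for unidentifiable directions.
polish_gauss_newton <- function(resid_fn, best, lower, upper, max_iter = 5) {
  par <- best$par
  dev <- best$deviance
  for (it in seq_len(max_iter)) {
    step <- tryCatch({
      r <- resid_fn(par)
      J <- pracma::jacobian(resid_fn, par)
      -solve(crossprod(J), crossprod(J, r))
    }, error = function(e) NULL)
    if (is.null(step) || !all(is.finite(step))) break
    cand <- pmin(pmax(par + as.numeric(step), lower), upper)
    dev_cand <- sum(resid_fn(cand)^2)
    # near the optimum the deviance is flat at machine precision while the
    # GN fixed point is the analytically accurate one, so a relative wobble
    # of 1e-9 is tolerated when accepting the step
    if (!is.finite(dev_cand) || dev_cand > dev * (1 + 1e-9)) break
    converged_step <- all(abs(cand - par) <= 1e-12 * (abs(par) + 1e-12))
    par <- cand
    dev <- dev_cand
    if (converged_step) break
  }
  best$par <- par
  best$deviance <- dev
  best
}

# Gauss-Newton standard errors: sigma^2 (J'J)^-1 with a numerical Jacobian of
# the mean function at the public estimates.
fit_std_errors <- function(predict_fn, data, estimates, rss, n_obs) {
  p <- length(estimates)
  se <- rep(NA_real_, p)
  if (n_obs <= p) return(stats::setNames(se, names(estimates)))
  J <- tryCatch(
    pracma::jacobian(function(par) predict_fn(par, data), as.numeric(estimates)),
    error = function(e) NULL
  )
  if (!is.null(J) && all(is.finite(J))) {
    sigma2 <- rss / (n_obs - p)
    cov <- tryCatch(solve(crossprod(J)) * sigma2, error = function(e) NULL)
    if (!is.null(cov)) {
      d <- diag(cov)
      se[d >= 0] <- sqrt(d[d >= 0])
    }
  }
  stats::setNames(se, names(estimates))
}

#' Fit a TPC model by multistart bounded nonlinear least squares
#'
#' Draws `n_starts` start vectors uniformly from the model's start ranges
#' (seeded, so results are fully reproducible), runs bounded
#' Levenberg-Marquardt least squares from each, and keeps the converged
#' solution with the smallest residual sum of squares.
#'
#' @param spec A `tpc_model_spec` from [model_spec()] (a model name is also
#'   accepted).
#' @param temp Temperatures in degC.
#' @param speed Response values (m/s); must be non-negative.
#' @param n_starts Number of random starts (default 250).
#' @param seed Integer seed for the start draws.
#' @return A `tpc_fit` object: estimates, standard errors, `rss`, `n_obs`,
#'   `n_params`, `aic`, convergence diagnostics, and the data/prediction
#'   closure needed by [residual_table()], [wald_ci()] and [bootstrap_ci()].
#' @examples
#' temp <- seq(8, 32, length.out = 14)
#' sp <- eval_model("gaussian", c(0.05, 26, 6), temp)
#' fit <- fit_multistart(model_spec("gaussian"), temp, sp, n_starts = 20, seed = 1)
#' coef(fit)
#' @export
fit_multistart <- function(spec, temp, speed, n_starts = 250, seed = 1) {
  if (is.character(spec)) spec <- model_spec(spec)
  stopifnot(inherits(spec, "tpc_model_spec"))
  if (length(temp) != length(speed)) stop("temp and speed lengths differ")
  keep <- is.finite(temp) & is.finite(speed)
  temp <- temp[keep]; speed <- speed[keep]
  if (any(speed < 0)) stop("speed values must be non-negative")
  if (length(speed) < spec$n_params + 2) {
    stop(sprintf("model '%s' needs at least %d observations, got %d",
                 spec$name, spec$n_params + 2, length(speed)))
  }
  predict_fn <- local({
    fn <- spec$fn
    nm <- spec$param_names
    function(par, data) fn(stats::setNames(as.numeric(par), nm), data$temp)
  })
  ls_multistart(spec, predict_fn, list(temp = temp), speed, n_starts, seed)
}

#' @export
coef.tpc_fit <- function(object, ...) object$estimates

#' @export
residuals.tpc_fit <- function(object, ...) object$response - object$fitted

#' @export
fitted.tpc_fit <- function(object, ...) object$fitted

#' @export
print.tpc_fit <- function(x, ...) {
  cat(sprintf("Multistart NLS fit: %s (n = %d, %d/%d starts converged)\n",
              x$model_name, x$n_obs, x$n_starts_converged, x$n_starts))
  print(fit_summary(x), row.names = FALSE, digits = 4)
  cat(sprintf("RSS = %.6g, AIC = %.4f\n", x$rss, x$aic))
  invisible(x)
}

#' Parameter summary table for a fit
#'
#' One row per parameter with estimate, standard error, Wald confidence
#' interval and two-sided t-test p-value on `n_obs - n_params` degrees of
#' freedom.
#'
#' @param fit A `tpc_fit`.
#' @param level Confidence level (default 0.95).
#' @return A data.frame with columns `parameter`, `estimate`, `std_error`,
#'   `ci_lower`, `ci_upper`, `p_value`.
#' @export
fit_summary <- function(fit, level = 0.95) {
  ci <- wald_ci(fit, level)
  df <- fit$n_obs - fit$n_params
  tstat <- fit$estimates / fit$std_errors
  p <- 2 * stats::pt(-abs(tstat), df)
  data.frame(
    parameter = names(fit$estimates),
    estimate = as.numeric(fit$estimates),
    std_error = as.numeric(fit$std_errors),
    ci_lower = ci$lower,
    ci_upper = ci$upper,
    p_value = as.numeric(p),
    row.names = NULL
  )
}

#' Wald confidence intervals for fitted parameters
#'
#' `estimate +/- z(level) * std_error`. Parameters with non-finite standard
#' errors get NA intervals.
#'
#' @param fit A `tpc_fit`.
#' @param level Confidence level in `[0, 1)`; `level = 0` gives degenerate
#'   point intervals.
#' @return Data.frame with `parameter`, `estimate`, `lower`, `upper`.
#' @export
wald_ci <- function(fit, level = 0.95) {
  z <- stats::qnorm(1 - (1 - level) / 2)
  se <- as.numeric(fit$std_errors)
  est <- as.numeric(fit$estimates)
  half <- z * se
  data.frame(
    parameter = names(fit$estimates),
    estimate = est,
    lower = est - half,
    upper = est + half,
    row.names = NULL
  )
}

#' Case-resampling bootstrap confidence intervals
#'
#' Resamples observations with replacement, refits each replicate by a single
#' bounded least-squares run started from the original estimates, and reports
#' percentile intervals. Unlike Wald intervals these can be asymmetric around
#' the estimates, which matters for weakly identified parameters such as the
#' deactivation energy.
#'
#' @param fit A `tpc_fit`.
#' @param B Number of bootstrap replicates (at least 100).
#' @param seed Integer seed.
#' @param level Confidence level (default 0.95).
#' @return Data.frame with `parameter`, `estimate`, `lower`, `upper`, plus
#'   attributes `n_failed` (non-converged replicates) and a warning when more
#'   than 20% of replicates fail.
#' @export
bootstrap_ci <- function(fit, B = 500, seed = 1, level = 0.95) {
  if (B < 100) stop("B must be at least 100")
  spec <- fit$spec
  start_int <- spec$to_internal(as.numeric(fit$estimates))
  ctrl <- minpack.lm::nls.lm.control(ftol = 1e-12, ptol = 1e-12, maxiter = 500)
  n <- fit$n_obs

  old_seed <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, envir = globalenv()))
  set.seed(seed)

  draws <- matrix(NA_real_, nrow = B, ncol = fit$n_params)
  n_failed <- 0L
  for (b in seq_len(B)) {
    idx <- sample.int(n, n, replace = TRUE)
    data_b <- lapply(fit$data, function(col) col[idx])
    resp_b <- fit$response[idx]
    rfun <- local({
      from_internal <- spec$from_internal
      rf <- ls_residual_fn(fit$predict_fn, data_b, resp_b)
      function(par) rf(from_internal(par))
    })
    refit <- tryCatch(
      minpack.lm::nls.lm(par = start_int, lower = spec$internal_lower,
                         upper = spec$internal_upper, fn = rfun, control = ctrl),
      error = function(e) NULL
    )
    if (is.null(refit) || !(refit$info %in% 1:4)) {
      n_failed <- n_failed + 1L
      next
    }
    draws[b, ] <- spec$from_internal(refit$par)
  }
  if (n_failed > 0.2 * B) {
    warning(sprintf("%d of %d bootstrap replicates failed to converge", n_failed, B))
  }
  alpha <- (1 - level) / 2
  qs <- apply(draws, 2, stats::quantile, probs = c(alpha, 1 - alpha), na.rm = TRUE)
  out <- data.frame(
    parameter = names(fit$estimates),
    estimate = as.numeric(fit$estimates),
    lower = qs[1, ],
    upper = qs[2, ],
    row.names = NULL
  )
  attr(out, "n_failed") <- n_failed
  attr(out, "B") <- B
  out
}

#' Fit and rank several TPC models by AIC
#'
#' Fits each named model with [fit_multistart()] and ranks the results by AIC
#' (ascending). Ties are broken by fewer parameters, then by name. A model
#' whose fit fails is recorded in its row rather than aborting the comparison.
#'
#' @param temp Temperatures in degC.
#' @param speed Response values (m/s).
#' @param names Models to compare (default: all five families).
#' @param n_starts,seed Passed to [fit_multistart()]; each model gets its own
#'   seed offset so the comparison is reproducible as a whole.
#' @return A `tpc_model_comparison` data.frame with columns `model`,
#'   `n_params`, `aic`, `delta_aic`, `ok`, `message`, plus attribute `fits`
#'   holding the individual `tpc_fit` objects.
#' @export
compare_models <- function(temp, speed, names = list_models(),
                           n_starts = 250, seed = 1) {
  rows <- lapply(seq_along(names), function(i) {
    nm <- names[[i]]
    fit <- tryCatch(
      fit_multistart(model_spec(nm), temp, speed,
                     n_starts = n_starts, seed = seed + i - 1L),
      error = function(e) e
    )
    if (inherits(fit, "error")) {
      list(model = nm, n_params = model_spec(nm)$n_params, aic = NA_real_,
           ok = FALSE, message = conditionMessage(fit), fit = NULL)
    } else {
      list(model = nm, n_params = fit$n_params, aic = fit$aic,
           ok = TRUE, message = "", fit = fit)
    }
  })
  tab <- data.frame(
    model = vapply(rows, `[[`, "", "model"),
    n_params = vapply(rows, `[[`, 0L, "n_params"),
    aic = vapply(rows, `[[`, 0, "aic"),
    ok = vapply(rows, `[[`, TRUE, "ok"),
    message = vapply(rows, `[[`, "", "message"),
    row.names = NULL
  )
  ord <- order(tab$aic, tab$n_params, tab$model, na.last = TRUE)
  tab <- tab[ord, , drop = FALSE]
  best <- min(tab$aic, na.rm = TRUE)
  tab$delta_aic <- tab$aic - best
  tab <- tab[, c("model", "n_params", "aic", "delta_aic", "ok", "message")]
  rownames(tab) <- NULL
  fits <- lapply(rows, `[[`, "fit")
  names(fits) <- vapply(rows, `[[`, "", "model")
  attr(tab, "fits") <- fits[tab$model]
  class(tab) <- c("tpc_model_comparison", "data.frame")
  tab
}

#' @export
print.tpc_model_comparison <- function(x, ...) {
  cat("TPC model comparison (ranked by AIC)\n")
  print(as.data.frame(x)[, c("model", "n_params", "aic", "delta_aic", "ok")],
        row.names = FALSE, digits = 6)
  invisible(x)
}
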