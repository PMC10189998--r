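test_that("noiseless gaussian data are recovered to numerical precision", {
  temp <- seq(8, 32, length.out = 25)
  truth <- c(r_max = 0.05, t_opt = 26, a = 6)
  sp <- eval_model("gaussian", truth, temp)
  fit <- fit_multistart(model_spec("gaussian"), temp, sp, n_starts = 30, seed = 1)
  expect_equal(as.numeric(coef(fit)), as.numeric(truth), tolerance = 1e-6)
  expect_lt(fit$rss, 1e-15)
})

test_that("under-determined fits and negative responses are refused", {
  expect_error(fit_multistart("pawar", c(10, 20, 30), c(0.01, 0.02, 0.01)),
               "at least")
  expect_error(fit_multistart("gaussian", 1:10, c(rep(0.01, 9), -0.01)),
               "non-negative")
})

test_that("the same seed gives a bit-identical fit", {
  set.seed(99)
  temp <- rep(seq(8, 32, length.out = 14), 3)
  sp <- eval_model("gaussian", c(0.05, 26, 6), temp) * exp(rnorm(length(temp), 0, 0.2))
  f1 <- fit_multistart("gaussian", temp, sp, n_starts = 25, seed = 42)
  f2 <- fit_multistart("gaussian", temp, sp, n_starts = 25, seed = 42)
  expect_identical(coef(f1), coef(f2))
  expect_identical(f1$rss, f2$rss)
  expect_identical(f1$std_errors, f2$std_errors)
})

test_that("AIC follows the nls convention and guards degenerate fits", {
  # residuals (1,-1,1,-1), one mean parameter: 4 log(2 pi) + 8
  expect_equal(aic_rss(4, 4, 1), 4 * log(2 * pi) + 8, tolerance = 1e-12)
  expect_equal(aic_rss(4, 4, 1), 15.3515083, tolerance = 1e-7)
  expect_error(aic_rss(0, 10, 2), "rss")

  # the additive n log(2 pi) + n constant cancels in differences
  d1 <- aic_rss(2, 20, 3) - aic_rss(5, 20, 4)
  d2 <- (20 * log(2 / 20) + 2 * 4) - (20 * log(5 / 20) + 2 * 5)
  expect_equal(d1, d2, tolerance = 1e-12)
})

test_that("AIC matches what R computes for an nls fit on the same data", {
  set.seed(3)
  temp <- seq(5, 35, length.out = 30)
  sp <- eval_model("gaussian", c(0.05, 25, 6), temp) + rnorm(30, 0, 0.003)
  sp <- pmax(sp, 0)
  fit <- fit_multistart("gaussian", temp, sp, n_starts = 30, seed = 1)
  ref <- stats::nls(sp ~ r * exp(-0.5 * ((temp - to) / a)^2),
                    start = list(r = 0.05, to = 25, a = 6))
  expect_equal(AIC(fit), AIC(ref), tolerance = 1e-6)
})

test_that("quadratic multistart fit equals the closed-form OLS solution", {
  set.seed(5)
  temp <- seq(8, 32, length.out = 40)
  sp <- pmax(0.01 + 0.004 * temp - 1e-4 * temp^2 + rnorm(40, 0, 0.002), 0)
  fit <- fit_multistart("quadratic", temp, sp, n_starts = 40, seed = 2)
  ols <- stats::lm(sp ~ temp + I(temp^2))
  expect_equal(as.numeric(coef(fit)), as.numeric(coef(ols)), tolerance = 1e-8)
  expect_equal(fit$rss, sum(resid(ols)^2), tolerance = 1e-10)
})

test_that("best RSS is non-increasing in the number of starts", {
  set.seed(8)
  temp <- rep(seq(8, 32, length.out = 14), 2)
  sp <- eval_model("pawar", c(0.05, 0.4, 3, 26), temp) *
    exp(rnorm(length(temp), 0, 0.3))
  rss <- vapply(c(5, 15, 40), function(ns) {
    fit_multistart("pawar", temp, sp, n_starts = ns, seed = 77)$rss
  }, numeric(1))
  expect_true(all(diff(rss) <= 1e-12))
})

test_that("Wald intervals are estimate +/- z * SE", {
  fit <- structure(list(estimates = c(E = 0.12), std_errors = c(E = 0.04),
                        n_obs = 20, n_params = 1), class = "tpc_fit")
  ci <- wald_ci(fit, 0.95)
  expect_equal(ci$lower, 0.12 - qnorm(0.975) * 0.04, tolerance = 1e-12)
  expect_equal(c(ci$lower, ci$upper), c(0.0416014, 0.1983986), tolerance = 1e-6)
  # level 0 collapses to the point estimate
  ci0 <- wald_ci(fit, 0)
  expect_equal(ci0$lower, ci0$upper)
})

test_that("bootstrap intervals are deterministic and collapse without noise", {
  temp <- seq(8, 32, length.out = 20)
  sp <- eval_model("gaussian", c(0.05, 26, 6), temp)
  fit <- fit_multistart("gaussian", temp, sp, n_starts = 20, seed = 1)
  b1 <- bootstrap_ci(fit, B = 120, seed = 5)
  b2 <- bootstrap_ci(fit, B = 120, seed = 5)
  expect_identical(b1, b2)
  expect_equal(b1$lower, as.numeric(coef(fit)), tolerance = 1e-6)
  expect_equal(b1$upper, as.numeric(coef(fit)), tolerance = 1e-6)
  expect_error(bootstrap_ci(fit, B = 50), "at least 100")
})

test_that("model comparison ranks by AIC with zero delta at the top", {
  set.seed(12)
  temp <- rep(seq(8, 32, length.out = 14), 3)
  sp <- eval_model("pawar", c(0.05, 0.4, 3, 26), temp) *
    exp(rnorm(length(temp), 0, 0.25))
  cmp <- compare_models(temp, sp, n_starts = 40, seed = 3)
  expect_equal(cmp$delta_aic[1], 0)
  expect_true(all(diff(cmp$aic) >= 0))
  expect_equal(sort(cmp$model), sort(list_models()))

  # single-model comparison: one row, delta 0
  one <- compare_models(temp, sp, names = "gaussian", n_starts = 20, seed = 3)
  expect_equal(nrow(one), 1)
  expect_equal(one$delta_aic, 0)
})

test_that("model ranking is invariant to reordering the data rows", {
  set.seed(21)
  temp <- rep(seq(8, 32, length.out = 14), 2)
  sp <- eval_model("pawar", c(0.05, 0.4, 3, 26), temp) *
    exp(rnorm(length(temp), 0, 0.25))
  perm <- sample(length(temp))
  c1 <- compare_models(temp, sp, n_starts = 40, seed = 9)
  c2 <- compare_models(temp[perm], sp[perm], n_starts = 40, seed = 9)
  expect_equal(c1$model[1], c2$model[1])
  expect_equal(c1$aic[order(c1$model)], c2$aic[order(c2$model)],
               tolerance = 1e-6)
})
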