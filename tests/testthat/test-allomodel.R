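test_that("closed-form identities of the combined model hold exactly", {
  p <- table2_truth()
  K0 <- 273.15
  k <- 8.617e-5

  # mass ratio: v(2M)/v(M) = 2^b at any temperature
  temps <- c(8, 15, 26.33, 32)
  expect_equal(eval_allo_tpc(p, 200, temps) / eval_allo_tpc(p, 100, temps),
               rep(2^0.12, 4), tolerance = 1e-12)
  expect_equal(eval_allo_tpc(p, 100, 20) / eval_allo_tpc(p, 10, 20),
               10^0.12, tolerance = 1e-12)

  # value at the optimum: denominator collapses to E_h / (E_h - E)
  M <- 105
  v_opt <- 0.03 * M^0.12 *
    exp(-0.37 / k * (1 / (26.33 + K0) - 1 / (15 + K0))) * (3.11 - 0.37) / 3.11
  expect_equal(eval_allo_tpc(p, M, 26.33), v_opt, tolerance = 1e-12)

  # at M = 1 mg and T = T_ref the prediction is a0 over a near-unity
  # denominator, confirming a0 as "speed of a 1 mg animal at 15 degC"
  den <- 1 + (0.37 / (3.11 - 0.37)) *
    exp(3.11 / k * (1 / (26.33 + K0) - 1 / (15 + K0)))
  expect_equal(eval_allo_tpc(p, 1, 15), 0.03 / den, tolerance = 1e-12)
  expect_lt(abs(eval_allo_tpc(p, 1, 15) - 0.03) / 0.03, 0.01)
})

test_that("invalid parameters and domains are rejected", {
  expect_error(allo_params(0.03, 0.12, 3.11, 0.37, 26), "E_h must exceed E")
  expect_error(allo_params(-1, 0.12, 0.37, 3.11, 26), "a0")
  expect_error(eval_allo_tpc(table2_truth(), -5, 20), "mass")
})

test_that("log speed is exactly linear in log mass at fixed temperature", {
  p <- table2_truth()
  masses <- exp(seq(log(10), log(303), length.out = 10))
  lv <- log(eval_allo_tpc(p, masses, 20))
  slope <- coef(lm(lv ~ log(masses)))[2]
  expect_equal(as.numeric(slope), 0.12, tolerance = 1e-12)
})

test_that("the combined curve peaks at t_opt for random valid parameters", {
  set.seed(4)
  for (i in 1:10) {
    E <- runif(1, 0.1, 1.5)
    p <- allo_params(runif(1, 0.005, 0.1), runif(1, -0.3, 0.8),
                     E, E + runif(1, 0.5, 8), runif(1, 12, 38))
    temp <- seq(p[["t_opt"]] - 20, p[["t_opt"]] + 20, by = 0.01)
    v <- eval_allo_tpc(p, 100, temp)
    expect_lt(abs(temp[which.max(v)] - p[["t_opt"]]), 0.015)
  }
})

test_that("noiseless records identify all five parameters", {
  truth <- table2_truth()
  d <- generate_speed_dataset(study_design(), truth,
                              noise_model(sigma = 0), seed = 3)
  fit <- fit_allo_tpc(d, n_starts = 40, seed = 1)
  expect_equal(as.numeric(coef(fit)), as.numeric(truth), tolerance = 1e-6)
})

test_that("degenerate designs raise identifiability errors", {
  d <- generate_speed_dataset(seed = 1)
  d_one_temp <- transform(d, temperature = 20)
  expect_error(fit_allo_tpc(d_one_temp), "unidentifiable")
  d_one_mass <- transform(d, mass = 100)
  expect_error(fit_allo_tpc(d_one_mass), "unidentifiable")
  expect_error(fit_allo_tpc(d[1:4, ]), "at least 7")
})

test_that("fixing b = 0 reduces the combined model to the pawar TPC", {
  set.seed(6)
  temp <- rep(seq(8, 32, length.out = 14), 3)
  sp <- eval_model("pawar", c(0.05, 0.4, 3, 26), temp) *
    exp(rnorm(length(temp), 0, 0.2))
  pw <- fit_multistart("pawar", temp, sp, n_starts = 60, seed = 2)
  # mass-free data: all masses 1 mg, so M^b = 1 for any b and the thermal
  # part must match the pure pawar fit
  recs <- data.frame(mass = c(1 + 1e-12, rep(1, length(temp) - 1)),
                     temperature = temp, speed = sp)
  al <- fit_allo_tpc(recs, n_starts = 60, seed = 2)
  expect_equal(al$rss, pw$rss, tolerance = 1e-8)
  expect_equal(as.numeric(coef(al)[c("E", "E_h", "t_opt")]),
               as.numeric(coef(pw)[c("E", "E_h", "t_opt")]), tolerance = 1e-4)
})

test_that("prediction grid is definitional, peaked at t_opt, monotone in mass", {
  p <- table2_truth()
  masses <- c(10, 105, 303)
  temps <- seq(8, 32, by = 0.25)
  g <- predict_grid(p, masses, temps)
  expect_equal(dim(g$speeds), c(3, length(temps)))
  expect_true(all(g$speeds > 0))
  expect_equal(g$speeds[2, 10], eval_allo_tpc(p, masses[2], temps[10]),
               tolerance = 1e-15)
  # column argmax at the grid temperature nearest t_opt, for every mass
  nearest <- which.min(abs(temps - p[["t_opt"]]))
  for (i in 1:3) expect_equal(unname(which.max(g$speeds[i, ])), nearest)
  # at fixed temperature speeds increase with mass (b > 0)
  expect_true(all(apply(g$speeds, 2, diff) > 0))
  # long format agrees
  long <- as.data.frame(g)
  expect_equal(nrow(long), 3 * length(temps))
  expect_equal(long$speed[long$mass == 105 & long$temperature == temps[10]],
               g$speeds[2, 10])
})

test_that("residual table carries groups and is zero for noiseless data", {
  truth <- table2_truth()
  d0 <- generate_speed_dataset(study_design(), truth,
                               noise_model(sigma = 0), seed = 2)
  fit0 <- fit_allo_tpc(d0, n_starts = 40, seed = 1)
  rt <- residual_table(fit0)
  expect_equal(nrow(rt), nrow(d0))
  expect_true(all(c("species", "habitat_group", "residual") %in% names(rt)))
  expect_lt(max(abs(rt$residual)), 1e-7)
})

test_that("an unbiased fit on symmetric noise has near-zero mean residual", {
  d <- generate_speed_dataset(study_design(), table2_truth(),
                              noise_model(kind = "gaussian", sigma = 0.01),
                              seed = 9)
  fit <- fit_allo_tpc(d, n_starts = 60, seed = 1)
  rt <- residual_table(fit)
  se_mean <- sd(rt$residual) / sqrt(nrow(rt))
  expect_lt(abs(mean(rt$residual)), 2 * se_mean)
})
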