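test_that("mixture prediction hits endpoints exactly and the worked midpoint", {
  for (f in c(0.25, 1, 2, 4)) {
    expect_equal(predict_titration_charge(100, 90, 10, f), 90)
    expect_equal(predict_titration_charge(0, 90, 10, f), 10)
  }
  # p=50, T_A=90, T_B=10, F=2: (50*90 + 50*10*2) / (50 + 50*2) = 5500/150
  expect_equal(predict_titration_charge(50, 90, 10, 2), 5500 / 150)
  expect_error(predict_titration_charge(0, 90, 10, 0), "denominator")
})

test_that("mixture prediction is monotone in p and linear at F=1", {
  p <- seq(0, 100, by = 5)
  for (f in c(0.25, 0.5, 1, 2, 4)) {
    v <- predict_titration_charge(p, 90, 10, f)
    expect_true(all(diff(v) > 0))
  }
  expect_equal(predict_titration_charge(p, 90, 10, 1),
               (p * 90 + (100 - p) * 10) / 100)
})

test_that("noise-free titration recovers F exactly", {
  for (f in c(0.5, 1, 2)) {
    dat <- simulate_titration("tx1", F_true = f, T_A_true = 90, T_B_true = 10,
                              noise_sd = 0, seed = 1)
    fit <- fit_correction_factors(dat)
    expect_lt(abs(fit$F_i - f), 1e-6)
    expect_false(fit$at_bound)
  }
})

test_that("noisy titration recovers F within 0.15", {
  for (f in c(0.5, 1, 2)) {
    dat <- simulate_titration("tx1", F_true = f, T_A_true = 90, T_B_true = 10,
                              n_reps = 4, noise_sd = 1, seed = 42 + f * 10)
    fit <- fit_correction_factors(dat)
    expect_lt(abs(fit$F_i - f), 0.15)
  }
})

test_that("F outside the bounds is clipped at the bound and flagged", {
  dat <- simulate_titration("tx1", F_true = 10, T_A_true = 90, T_B_true = 10,
                            noise_sd = 0, seed = 1)
  fit <- fit_correction_factors(dat)
  expect_equal(fit$F_i, 4)
  expect_true(fit$at_bound)
})

test_that("titration fit exposes modelling-idiom methods", {
  dat <- simulate_titration(c("tx1", "tx2"), F_true = c(1, 2), noise_sd = 0,
                            seed = 2)
  fit <- fit_correction_factors(dat)
  expect_s3_class(fit, "titration_fit")
  expect_named(coef(fit), c("tx1", "tx2"))
  pred <- predict(fit, data.frame(transcript = "tx1", ratio_p = 100))
  expect_equal(pred, fit$T_A[fit$transcript == "tx1"])
  expect_output(print(fit), "correction-factor")
})

test_that("error report medians are zero without noise, bins partition", {
  dat <- simulate_titration(c("tx1", "tx2"), F_true = c(0.5, 2), noise_sd = 0,
                            seed = 3)
  fit <- fit_correction_factors(dat)
  rep0 <- titration_error_report(fit, dat, "adapter")
  expect_true(all(abs(rep0$median_err) < 1e-6))
  expect_equal(sum(rep0$n), sum(dat$ratio_p > 0 & dat$ratio_p < 100))
})

test_that("a planted adapter bias shows up in its error bin", {
  dat <- simulate_titration(sprintf("tx%d", 1:5), F_true = 1,
                            n_reps = 4, noise_sd = 1,
                            adapter_bias = c(I1Sp = 0, I2Sp = 0, I3Sp = 0,
                                             I4Sp = 3),
                            seed = 11)
  fit <- fit_correction_factors(dat)
  rep <- titration_error_report(fit, dat, "adapter")
  biased <- rep$median_err[rep$bin == "I4Sp"]
  expect_gt(biased, 2)
  expect_lt(biased, 4)
  expect_true(all(abs(rep$median_err[rep$bin != "I4Sp"]) < 1.5))
})

test_that("decay curve evaluates its closed form", {
  expect_equal(decay_value(0, 90, 120, 2), 92)
  expect_equal(decay_value(120, 90, 120, 2), 47)
  expect_equal(decay_value(20 * 120, 90, 120, 2), 90 * 0.5^20 + 2)
  expect_equal(decay_value(20 * 120, 90, 120, 2), 2.0000858306884766)
  # strictly decreasing in t for N0 > 0
  t <- seq(0, 2400, by = 10)
  expect_true(all(diff(decay_value(t, 90, 120, 2)) < 0))
})

test_that("noise-free decay series recovers parameters to 1e-4 relative", {
  params <- data.frame(group = "g1", N0 = 90, t_half = 120, N_inf = 2)
  series <- simulate_decay(params, noise_sd = 0, seed = 1)
  fit <- fit_decay(series)
  expect_lt(abs(fit$N0 - 90) / 90, 1e-4)
  expect_lt(abs(fit$t_half - 120) / 120, 1e-4)
  expect_lt(abs(fit$N_inf - 2) / 2, 1e-3 * 5)
  expect_equal(fit$charge_t0, fit$N0 + fit$N_inf)
  # objective at fit <= objective at truth
  rss_truth <- sum((decay_value(series$time_min, 90, 120, 2) - series$charge)^2)
  expect_lte(fit$rss, rss_truth + 1e-8)
})

test_that("noisy decay recovers the half-life within 10% relative", {
  params <- data.frame(group = sprintf("g%d", 1:5),
                       N0 = c(90, 80, 70, 85, 60),
                       t_half = c(30, 120, 480, 1000, 240),
                       N_inf = c(2, 1, 3, 0.5, 2))
  series <- simulate_decay(params, noise_sd = 1, seed = 7)
  fit <- fit_decay(series)
  rel <- abs(fit$t_half - params$t_half) / params$t_half
  expect_true(all(rel < 0.10))
})

test_that("a non-decaying series pins the half-life at a bound, flagged", {
  flat <- expand.grid(group = "flat", time_min = c(0, 10, 100, 1000),
                      replicate = 1:3)
  flat$charge <- 80
  fit <- fit_decay(flat)
  expect_true(fit$t_half_at_bound)
})

test_that("decay fit exposes modelling-idiom methods", {
  params <- data.frame(group = c("a", "b"), N0 = c(90, 70),
                       t_half = c(60, 600), N_inf = c(1, 2))
  series <- simulate_decay(params, noise_sd = 0, seed = 2)
  fit <- fit_decay(series)
  cm <- coef(fit)
  expect_equal(rownames(cm), c("a", "b"))
  expect_equal(unname(cm[, "t_half"]), c(60, 600), tolerance = 1e-4)
  pred <- predict(fit, data.frame(group = "a", time_min = 0))
  expect_equal(pred, 91, tolerance = 1e-3)
  expect_output(print(fit), "t_half range")
})

test_that("bootstrap CIs are zero-width without noise and seed-stable", {
  params <- data.frame(group = "g1", N0 = 90, t_half = 120, N_inf = 2)
  series <- simulate_decay(params, noise_sd = 0, seed = 1)
  ci <- bootstrap_decay_ci(series, n_boot = 50, seed = 5)
  expect_lt(ci$t_half_hi - ci$t_half_lo, 1e-4)
  noisy <- simulate_decay(params, noise_sd = 1, seed = 3)
  c1 <- bootstrap_decay_ci(noisy, n_boot = 100, seed = 9)
  c2 <- bootstrap_decay_ci(noisy, n_boot = 100, seed = 9)
  expect_identical(c1, c2)
  c3 <- bootstrap_decay_ci(noisy, n_boot = 100, seed = 10)
  expect_false(identical(c1, c3))
})

test_that("bootstrap t_half CI covers the truth for most groups", {
  n_groups <- 12
  set.seed(99)
  params <- data.frame(group = sprintf("g%02d", 1:n_groups),
                       N0 = runif(n_groups, 50, 95),
                       t_half = exp(runif(n_groups, log(20), log(2000))),
                       N_inf = runif(n_groups, 0, 3))
  series <- simulate_decay(params, noise_sd = 1, seed = 13)
  ci <- bootstrap_decay_ci(series, n_boot = 200, seed = 17)
  covered <- ci$t_half_lo <= params$t_half & params$t_half <= ci$t_half_hi
  expect_gte(mean(covered), 0.9)
})
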