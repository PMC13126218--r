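test_that("ICC and random-intercept variance convert exactly both ways", {
  expect_equal(icc_to_variance(0), 0)
  expect_equal(icc_to_variance(0.20), 0.25 * pi^2 / 3)
  expect_equal(icc_to_variance(0.20), 0.822467, tolerance = 1e-6)
  expect_equal(icc_to_variance(0.05), (0.05 / 0.95) * pi^2 / 3)
  expect_equal(icc_to_variance(0.05), 0.173151, tolerance = 1e-6)
  for (icc in c(0.01, 0.05, 0.2, 0.5, 0.9)) {
    expect_equal(variance_to_icc(icc_to_variance(icc)), icc)
  }
  expect_error(icc_to_variance(1), "\\[0, 1\\)")
})

test_that("the c-statistic matches an independent implementation", {
  withr::with_seed(30, {
    p <- runif(500)
    y <- rbinom(500, 1, p)
  })
  expect_equal(cstat(p, y),
               as.numeric(suppressMessages(
                 pROC::auc(y, p, direction = "<", quiet = TRUE))))
  expect_equal(cstat(c(0.9, 0.1), c(1, 0)), 1)
  expect_equal(cstat(c(0.5, 0.5), c(1, 0)), 0.5)
})

test_that("intercept calibration solves the closed-form case", {
  b0 <- calibrate_intercept_for_rate(0.5, beta1 = 0, sigma_u2 = 0,
                                     mc_n = 1000, seed = 1)
  expect_equal(b0, 0, tolerance = 1e-6)
  b0_3 <- calibrate_intercept_for_rate(0.3, beta1 = 0, sigma_u2 = 0,
                                       mc_n = 1000, seed = 1)
  expect_equal(b0_3, logit(0.3), tolerance = 1e-6)
})

test_that("with heterogeneity the intercept compensates the Jensen effect", {
  b0 <- calibrate_intercept_for_rate(0.3, beta1 = 1, sigma_u2 = 1,
                                     mc_n = 200000, seed = 2)
  expect_lt(b0, logit(0.3))
  d <- clustercal:::mc_draws(200000, 1, seed = 99)
  expect_equal(mean(expit(b0 + d$x + d$u)), 0.3, tolerance = 0.005)
})

test_that("slope calibration is monotone in the AUC target and verifies", {
  b_low <- calibrate_slope_for_auc(0.75, sigma_u2 = 0.173, mc_n = 100000,
                                   seed = 3)
  b_high <- calibrate_slope_for_auc(0.90, sigma_u2 = 0.173, mc_n = 100000,
                                    seed = 3)
  expect_gt(b_high, b_low)
  d <- clustercal:::mc_draws(200000, 0.173, seed = 77)
  tp <- expit(b_low * d$x + d$u)
  expect_equal(cstat(tp, as.integer(d$uy < tp)), 0.75, tolerance = 0.01)
})

test_that("superpopulations are reproducible and match their parameters", {
  spec <- superpopulation_spec(icc = 0.2, auc = 0.75, event_rate = 0.3,
                               n_clusters = 20, n_per_cluster = 500,
                               mc_n = 100000, seed = 5)
  expect_equal(spec$sigma_u2, icc_to_variance(0.2))
  sp1 <- make_superpopulation(spec)
  sp2 <- make_superpopulation(spec)
  expect_identical(sp1$data, sp2$data)
  expect_equal(nrow(sp1$data), 20 * 500)
  expect_equal(length(sp1$u), 20)
  expect_equal(sp1$data$true_p,
               expit(spec$beta0 + spec$beta1 * sp1$data$x +
                       sp1$u[sp1$data$cluster]),
               ignore_attr = TRUE)
})

test_that("zero heterogeneity equalises cluster prevalences", {
  spec <- superpopulation_spec(icc = 0, auc = 0.75, event_rate = 0.3,
                               n_clusters = 30, n_per_cluster = 10000,
                               mc_n = 100000, seed = 6)
  sp <- make_superpopulation(spec)
  prevs <- tapply(sp$data$y, sp$data$cluster, mean)
  expect_lt(stats::sd(prevs), 0.01)
})

test_that("scenario draws follow the events-per-cluster sizing rule", {
  spec <- superpopulation_spec(icc = 0.2, auc = 0.75, event_rate = 0.3,
                               n_clusters = 12, n_per_cluster = 2000,
                               mc_n = 100000, seed = 7)
  sp <- make_superpopulation(spec)
  sam <- draw_scenario(sp, n_clusters = 4, epc = 20, seed = 8)
  prevs <- tapply(sp$data$y, sp$data$cluster, mean)
  sizes <- table(sam$cluster)
  for (cl in names(sizes)) {
    expect_equal(as.integer(sizes[[cl]]),
                 as.integer(ceiling(20 * 1.15 / prevs[[cl]])))
  }
  expect_true(all(names(sizes) %in% names(sp$u)))
  # the stated arithmetic: epc 20 at prevalence 0.30 needs 77 rows
  expect_equal(ceiling(20 * 1.15 / 0.30), 77)
  expect_equal(ceiling(200 * 1.15 / 0.50), 460)
  expect_error(draw_scenario(sp, n_clusters = 50, epc = 20, seed = 1),
               "more clusters")
})

test_that("trained predictors recover the true risk surface", {
  spec <- superpopulation_spec(icc = 0, auc = 0.75, event_rate = 0.3,
                               n_clusters = 5, n_per_cluster = 10000,
                               mc_n = 100000, seed = 9)
  sp <- make_superpopulation(spec)
  pred <- train_prediction_model(sp$data)
  phat <- predict(pred, sp$data)
  expect_true(all(phat > 0 & phat < 1))
  expect_lt(mean((phat - sp$data$true_p)^2), 1e-3)
  expect_error(train_prediction_model(tibble::tibble(x = rnorm(30),
                                                     y = rep(1, 30))),
               "both outcome classes")
})

test_that("the true curve self-inverts and is monotone in the intercept", {
  spec <- superpopulation_spec(icc = 0.2, auc = 0.75, event_rate = 0.3,
                               n_clusters = 5, n_per_cluster = 100,
                               mc_n = 50000, seed = 10)
  # predictor that IS the average-cluster truth
  pred <- structure(
    list(model = clustercal:::new_fitted_curve_model(
      kind = "logistic_rcs",
      coefficients = c(spec$beta0, spec$beta1, 0),
      coef_cov = diag(1e-6, 3), knots = c(-1, 0, 1),
      n_obs = 100, x_range = c(-4, 4)),
      knots = c(-1, 0, 1), x_range = c(-4, 4)),
    class = "risk_predictor")
  grid <- seq(0.05, 0.9, by = 0.05)
  tc0 <- true_curve(spec, pred, grid, u = 0)
  expect_equal(tc0, grid, tolerance = 1e-4)
  tc_up <- true_curve(spec, pred, grid, u = 0.5)
  expect_true(all(tc_up > tc0))
  # grid points beyond the attainable range come back missing
  wide <- true_curve(spec, pred, c(1e-6, grid), u = 0)
  expect_true(is.na(wide[1]))
})

test_that("inversion agrees with the empirical window estimate", {
  # at ICC 0 the marginal window average is the average-cluster truth
  spec <- superpopulation_spec(icc = 0, auc = 0.75, event_rate = 0.3,
                               n_clusters = 50, n_per_cluster = 4000,
                               mc_n = 100000, seed = 11)
  sp <- make_superpopulation(spec)
  pred <- train_prediction_model(sp$data[1:50000, ])
  grid <- c(0.2, 0.3, 0.4, 0.5)
  inv <- true_curve(spec, pred, grid, u = 0)
  phat <- predict(pred, sp$data)
  emp <- vapply(grid, function(g) {
    w <- abs(phat - g) <= 0.005
    mean(sp$data$true_p[w])
  }, numeric(1))
  expect_equal(inv, emp, tolerance = 0.01)
})

test_that("non-linear superpopulations keep the target event rate", {
  spec <- superpopulation_spec(icc = 0.05, auc = 0.75, event_rate = 0.3,
                               n_clusters = 100, n_per_cluster = 2000,
                               mc_n = 100000, seed = 12)
  spnl <- make_nonlinear_superpopulation(spec, "quadratic", beta2 = 0.5,
                                         mc_n = 100000)
  expect_equal(mean(spnl$data$y), 0.3, tolerance = 0.01)
  expect_lt(spnl$spec$beta0, spec$beta0)  # x^2 term raises risk, intercept drops

  # beta2 = 0 reduces exactly to the linear generator
  spz <- make_nonlinear_superpopulation(spec, "quadratic", beta2 = 0,
                                        mc_n = 100000)
  splin <- make_superpopulation(spz$spec)
  expect_identical(spz$data, splin$data)

  sp_a <- make_nonlinear_superpopulation(spec, "step_mix", beta2 = 0.4,
                                         mc_n = 50000)
  sp_b <- make_nonlinear_superpopulation(spec, "step_mix", beta2 = 0.4,
                                         mc_n = 50000)
  expect_identical(sp_a$data, sp_b$data)
})
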