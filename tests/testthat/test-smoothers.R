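test_that("link functions are exact and mutually inverse", {
  expect_equal(logit(0.5), 0)
  expect_equal(expit(0), 0.5)
  expect_equal(logit(0.3), log(3 / 7))
  p <- seq(0.01, 0.99, by = 0.01)
  expect_equal(expit(logit(p)), p, tolerance = 1e-14)
  expect_error(logit(0), "strictly inside")
  expect_error(logit(1.2), "strictly inside")
})

test_that("knots land on the conventional quantiles", {
  x <- 1:100
  expect_equal(place_knots(x, 3),
               unname(stats::quantile(x, c(0.10, 0.50, 0.90))))
  expect_equal(place_knots(x, 3), c(10.9, 50.5, 90.1))
  expect_equal(place_knots(x, 5),
               unname(stats::quantile(x, c(0.05, 0.275, 0.50, 0.725, 0.95))))
  expect_error(place_knots(rep(1, 50), 3), "distinct")
})

test_that("restricted cubic basis is truncated below and matches the formula", {
  kn <- c(0, 1, 2)
  expect_equal(rcs_basis(kn[1], kn)[1, ], c(x = 0, rcs1 = 0))
  expect_equal(unname(rcs_basis(-3, kn)[1, ]), c(-3, 0))
  # direct evaluation of the restricted-cubic term at x = 1.5
  x <- 1.5
  direct <- (max(x - 0, 0)^3 - max(x - 1, 0)^3 * (2 - 0) / (2 - 1) +
               max(x - 2, 0)^3 * (1 - 0) / (2 - 1)) / (2 - 0)^2
  expect_equal(unname(rcs_basis(x, kn)[1, 2]), direct)
  expect_error(rcs_basis(1, c(0, 0, 1)), "strictly increasing")
})

test_that("spline basis is linear beyond the outer knots", {
  kn <- place_knots(rnorm(200), 3)
  xs <- seq(kn[3] + 0.5, kn[3] + 3, length.out = 10)
  B <- rcs_basis(xs, kn)
  # second differences of every column vanish where the function is linear
  expect_lt(max(abs(diff(diff(B[, 2])))), 1e-10)
})

test_that("logistic fitting recovers closed-form and simulated truths", {
  y <- rep(c(1, 0), c(30, 70))
  fit <- fit_logistic(y, matrix(1, 100, 1))
  expect_equal(unname(fit$coefficients), logit(0.3), tolerance = 1e-8)

  withr::with_seed(42, {
    x <- rnorm(50000)
    yy <- rbinom(50000, 1, expit(x))
  })
  fit2 <- fit_logistic(yy, cbind(1, x))
  expect_lt(abs(fit2$coefficients[2] - 1), 0.05)
  expect_false(fit2$separated)
})

test_that("one-class data triggers the separation fallback", {
  x <- rnorm(50)
  expect_warning(fit <- fit_logistic(rep(1, 50), cbind(1, x)), "separation")
  expect_true(fit$separated)
  expect_true(all(is.finite(fit$coefficients)))
})

test_that("rank-deficient designs are rejected", {
  x <- rnorm(30)
  expect_error(fit_logistic(rbinom(30, 1, 0.5), cbind(1, x, 2 * x)),
               "rank deficient")
})

test_that("knot selection keeps 3 knots under a linear truth", {
  hits <- withr::with_seed(7, {
    vapply(1:20, function(i) {
      x <- rnorm(2000)
      y <- rbinom(2000, 1, expit(x))
      length(select_rcs_knots(y, x)$knots) == 3
    }, logical(1))
  })
  expect_gte(mean(hits), 0.8)
})

test_that("knot selection detects strong curvature", {
  hits <- withr::with_seed(8, {
    vapply(1:10, function(i) {
      x <- rnorm(5000)
      y <- rbinom(5000, 1, expit(0.4 * x^3))
      length(select_rcs_knots(y, x)$knots) > 3
    }, logical(1))
  })
  expect_gt(mean(hits), 0.5)
})

test_that("candidate knot set shrinks when x has few distinct values", {
  x <- rep(c(-1, -0.5, 0, 0.5), 30)
  y <- withr::with_seed(1, rbinom(length(x), 1, expit(x)))
  fit <- select_rcs_knots(y, x)
  expect_lte(length(fit$knots), 4)
})

test_that("LOESS is constant on constant data and AICc matches a rebuild", {
  x <- seq(-2, 2, length.out = 60)
  fit0 <- fit_loess(rep(1, 60), x, span = 0.7)
  pr <- predict_observed_proportion(fit0, seq(0.2, 0.8, by = 0.1))
  expect_lt(max(abs(pr$estimate - (1 - 1e-5))), 1e-6)

  # smoother-matrix rebuild: loess is linear in y, so column i of L is the
  # fit to the i-th indicator response
  withr::with_seed(3, {
    y <- rbinom(60, 1, expit(x))
  })
  fit <- fit_loess(y, x, span = 0.8)
  L <- vapply(seq_along(x), function(i) {
    e <- numeric(length(x)); e[i] <- 1
    stats::fitted(stats::loess(
      e ~ x, span = 0.8, degree = 2,
      control = stats::loess.control(surface = "direct")))[i]
  }, numeric(1))
  tr <- sum(L)
  n <- length(x)
  sigma2 <- mean(stats::residuals(fit$fit)^2)
  aicc <- n * log(sigma2) + n * (n + tr) / (n - tr - 2)
  expect_equal(fit$aicc, aicc, tolerance = 0.02)
})

test_that("span selection prefers smooth fits under a linear truth", {
  picks <- withr::with_seed(9, {
    vapply(1:10, function(i) {
      x <- rnorm(200)
      y <- rbinom(200, 1, expit(x))
      select_span(y, x)
    }, numeric(1))
  })
  expect_gt(mean(picks >= 0.6), 0.5)
})

test_that("prediction on the identity model returns the diagonal", {
  m <- clustercal:::new_fitted_curve_model(
    kind = "logistic_linear", coefficients = c(0, 1),
    coef_cov = diag(c(0.01, 0.01)), n_obs = 100, x_range = c(-3, 3))
  grid <- seq(0.05, 0.95, by = 0.05)
  pr <- predict_observed_proportion(m, grid)
  expect_equal(pr$estimate, grid, tolerance = 1e-12)
  expect_true(all(pr$se_logit > 0))
  # delta-method oracle at one point
  xg <- logit(0.3)
  v <- c(1, xg) %*% diag(c(0.01, 0.01)) %*% c(1, xg)
  expect_equal(pr$se_logit[grid == 0.3], sqrt(drop(v)))
  expect_error(predict_observed_proportion(m, c(0.5, 1)), "inside")
})
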