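make_identity_fit <- function(Sigma_u = matrix(0, 3, 3),
                              fixed_cov = diag(1e-4, 3)) {
  eb <- matrix(0, 2, 3, dimnames = list(c("A", "B"), NULL))
  structure(list(fixed = c(0, 1, 0), fixed_cov = fixed_cov,
                 Sigma_u = Sigma_u, eb = eb, knots = c(-1.5, 0, 1.5),
                 loglik_laplace = NA_real_, converged = TRUE,
                 messages = character(0), diagonal_fallback = FALSE,
                 level = 0.95, fit = NULL), class = "mixc_fit")
}

test_that("identity fixed effects give the diagonal average curve", {
  curve <- mixc_curves(make_identity_fit(), grid = seq(0.05, 0.95, 0.05),
                       n_draws = 200, seed = 1)
  expect_equal(curve$estimate, curve$grid, tolerance = 1e-12)
})

test_that("zero random-effects covariance collapses the PI onto the CI", {
  curve <- mixc_curves(make_identity_fit(), n_draws = 200, seed = 1)
  expect_equal(curve$pi_lo, curve$ci_lo)
  expect_equal(curve$pi_hi, curve$ci_hi)
})

test_that("PI percentiles are stable across seeds at 10000 draws", {
  fit <- make_identity_fit(Sigma_u = diag(c(0.2, 0.02, 0.005)),
                           fixed_cov = diag(1e-4, 3))
  c1 <- mixc_curves(fit, n_draws = 10000, seed = 1)
  c2 <- mixc_curves(fit, n_draws = 10000, seed = 2)
  # seed-to-seed difference can reach twice the single-run Monte-Carlo error
  expect_lt(max(abs(c1$pi_lo - c2$pi_lo)), 0.01)
  expect_lt(max(abs(c1$pi_hi - c2$pi_hi)), 0.01)
})

test_that("an indefinite covariance is projected before sampling", {
  bad <- matrix(c(0.5, 0.9, 0, 0.9, 0.5, 0, 0, 0, 0.1), 3, 3)
  fit <- make_identity_fit(Sigma_u = bad)
  expect_message(curve <- mixc_curves(fit, n_draws = 500, seed = 3),
                 "positive semi-definite")
  expect_true(all(curve$pi_lo <= curve$ci_lo))
})

test_that("near-homogeneous data yields a small random-effects covariance", {
  cp <- calibrated_cp(15, 300, seed = 23)
  fit <- fit_mixc(cp)
  expect_lt(norm(fit$Sigma_u, "F"), 0.3)
  curve <- mixc_curves(fit, n_draws = 500, seed = 1)
  pc <- attr(curve, "per_cluster")
  spread <- pc |>
    dplyr::group_by(grid) |>
    dplyr::summarise(s = max(estimate) - min(estimate))
  expect_lt(stats::median(spread$s), 0.1)
})

test_that("heterogeneity is picked up and EB curves shrink toward the mean", {
  cp <- make_fixture("heterogeneous", n_clusters = 10, n_per = 300,
                     seed = 24)
  fit <- fit_mixc(cp)
  expect_gt(fit$Sigma_u[1, 1], 0.1)
  expect_equal(nrow(fit$eb), 10)

  # a sparsely observed cluster shrinks: its EB curve sits between its own
  # independent fit and the average curve
  small_cl <- cp[cp$cluster == "C01", ][1:40, ]
  rest <- cp[cp$cluster != "C01", ]
  cp2 <- suppressWarnings(as_clustered_predictions(
    dplyr::bind_rows(small_cl, rest)))
  fit2 <- fit_mixc(cp2)
  grid <- seq(0.1, 0.9, by = 0.1)
  xg <- logit(grid)
  Xg <- cbind(1, rcs_basis(xg, fit2$knots))
  avg <- drop(Xg %*% fit2$fixed)
  ebc <- drop(Xg %*% (fit2$fixed + fit2$eb["C01", ]))
  own <- suppressWarnings(select_rcs_knots(small_cl$y, logit(small_cl$p)))
  ownc <- logit(clip_prob(
    predict_observed_proportion(own, grid)$estimate))
  # shrinkage: EB is closer to the average than the independent fit is
  expect_lt(mean(abs(ebc - avg)), mean(abs(ownc - avg)))
})

test_that("duplicating observations keeps estimates but sharpens them", {
  cp <- make_fixture("heterogeneous", n_clusters = 10, n_per = 400,
                     seed = 25)
  dup <- suppressWarnings(as_clustered_predictions(
    dplyr::bind_rows(cp, cp)))
  f1 <- fit_mixc(cp)
  f2 <- fit_mixc(dup)
  expect_lt(max(abs(f2$fixed - f1$fixed)), 0.05)
  expect_true(all(diag(f2$fixed_cov) < diag(f1$fixed_cov)))
})

test_that("mixc_fit accessors report convergence and heterogeneity", {
  cp <- calibrated_cp(5, 120, seed = 26)
  fit <- fit_mixc(cp)
  g <- glance(fit)
  expect_named(g, c("logLik", "sigma_u_frobenius", "n_clusters",
                    "converged", "diagonal_fallback"))
  expect_equal(g$n_clusters, 5)
  expect_equal(nrow(tidy(fit)), 3)
  expect_error(fit_mixc(calibrated_cp(1, 50, 1)), "at least 2 clusters")
})

test_that("the fast PIRLS variant tracks the Laplace fit closely", {
  cp <- make_fixture("heterogeneous", n_clusters = 8, n_per = 250, seed = 27)
  c1 <- cal_mixc(cp, grid_size = 30, n_draws = 500, seed = 1, nAGQ = 1)
  c0 <- cal_mixc(cp, grid_size = 30, n_draws = 500, seed = 1, nAGQ = 0)
  expect_lt(max(abs(c1$estimate - c0$estimate)), 0.02)
})
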