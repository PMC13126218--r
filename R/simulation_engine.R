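#' Convert between ICC and random-intercept variance
#'
#' On the logit scale the residual variance of a logistic model is
#' pi^2 / 3, so an intraclass correlation `icc` corresponds to a
#' random-intercept variance `sigma_u2 = icc / (1 - icc) * pi^2 / 3`, and
#' conversely `icc = sigma_u2 / (sigma_u2 + pi^2 / 3)`.
#'
#' @param icc Intraclass correlation in [0, 1).
#' @param sigma_u2 Random-intercept variance (>= 0).
#' @return The corresponding variance / ICC.
#' @export
icc_to_variance <- function(icc) {
  if (any(icc < 0 | icc >= 1)) stop("icc must lie in [0, 1)", call. = FALSE)
  icc / (1 - icc) * pi^2 / 3
}

#' @rdname icc_to_variance
#' @export
variance_to_icc <- function(sigma_u2) {
  stopifnot(all(sigma_u2 >= 0))
  sigma_u2 / (sigma_u2 + pi^2 / 3)
}

#' Empirical c-statistic (AUC)
#'
#' Rank-based concordance between predicted risks and binary outcomes; the
#' probability that a randomly chosen event has a higher prediction than a
#' randomly chosen non-event, with ties counted half.
#'
#' @param p Predicted risks or scores.
#' @param y Binary outcomes.
#' @return The c-statistic in [0, 1].
#' @export
cstat <- function(p, y) {
  stopifnot(length(p) == length(y), all(y %in% c(0, 1)))
  n1 <- as.numeric(sum(y == 1))
  n0 <- as.numeric(sum(y == 0))
  if (n1 == 0 || n0 == 0) stop("both outcome classes required", call. = FALSE)
  r <- rank(p)
  (sum(r[y == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

# Common-random-numbers Monte-Carlo sample used by the calibration
# root-finders: fixed standard-normal predictor, cluster deviate and
# outcome uniform per individual.
mc_draws <- function(mc_n, sigma_u2, seed) {
  withr::with_seed(seed, list(
    x = stats::rnorm(mc_n),
    u = stats::rnorm(mc_n, sd = sqrt(sigma_u2)),
    uy = stats::runif(mc_n)))
}

#' Calibrate the linear-predictor slope to a target AUC
#'
#' Finds the coefficient `beta1` of the standard-normal linear predictor
#' such that the c-statistic of the true probabilities against simulated
#' outcomes matches `auc_target`, by bracketed root-finding on a
#' Monte-Carlo estimate with common random numbers.
#'
#' @param auc_target Target AUC in (0.5, 1).
#' @param sigma_u2 Random-intercept variance of the data-generating model.
#' @param beta0 Intercept at which the AUC is evaluated.
#' @param mc_n Monte-Carlo sample size.
#' @param seed Integer seed for the common random numbers.
#' @return The calibrated `beta1` (>= 0).
#' @export
calibrate_slope_for_auc <- function(auc_target, sigma_u2, beta0 = 0,
                                    mc_n = 500000, seed = 1) {
  stopifnot(auc_target > 0.5, auc_target < 1)
  d <- mc_draws(mc_n, sigma_u2, seed)
  f <- function(b1) {
    tp <- expit(beta0 + b1 * d$x + d$u)
    cstat(tp, as.integer(d$uy < tp)) - auc_target
  }
  lo <- 1e-6
  hi <- 2
  while (f(hi) < 0 && hi < 20) hi <- hi * 2
  if (f(hi) < 0) stop("could not bracket beta1 in [0, 20]", call. = FALSE)
  stats::uniroot(f, c(lo, hi), tol = 1e-4)$root
}

#' Calibrate the intercept to a target event rate
#'
#' Finds `beta0` such that the Monte-Carlo mean of
#' `expit(beta0 + beta1 x + u)` equals the target marginal event rate.
#'
#' @param rate_target Target overall event rate in (0, 1).
#' @param beta1 Slope of the linear predictor.
#' @inheritParams calibrate_slope_for_auc
#' @return The calibrated `beta0`.
#' @export
calibrate_intercept_for_rate <- function(rate_target, beta1, sigma_u2,
                                         mc_n = 500000, seed = 1) {
  stopifnot(rate_target > 0, rate_target < 1)
  d <- mc_draws(mc_n, sigma_u2, seed)
  f <- function(b0) mean(expit(b0 + beta1 * d$x + d$u)) - rate_target
  stats::uniroot(f, c(-15, 15), tol = 1e-7)$root
}

#' Specify a clustered superpopulation
#'
#' Builds the full parameter set of a random-intercept logistic
#' data-generating model hitting the requested intraclass correlation,
#' discrimination and marginal event rate: the random-intercept variance is
#' obtained in closed form from the ICC, and the slope and intercept are
#' calibrated jointly by alternating Monte-Carlo root-finds (two passes,
#' which suffices because the AUC depends on the intercept only weakly).
#'
#' @param icc Target intraclass correlation in [0, 1).
#' @param auc Target AUC in (0.5, 1).
#' @param event_rate Target marginal event rate.
#' @param n_clusters,n_per_cluster Superpopulation dimensions (defaults
#'   200 clusters of 10,000).
#' @param mc_n Monte-Carlo size used during calibration.
#' @param seed Integer seed driving the calibration draws and, by default,
#'   the generation step.
#' @return A `superpopulation_spec` list with `beta0`, `beta1`, `sigma_u2`
#'   and the targets.
#' @export
superpopulation_spec <- function(icc, auc, event_rate = 0.3,
                                 n_clusters = 200, n_per_cluster = 10000,
                                 mc_n = 500000, seed = 1) {
  sigma_u2 <- icc_to_variance(icc)
  beta0 <- logit(event_rate)
  beta1 <- NA_real_
  for (pass in 1:2) {
    beta1 <- calibrate_slope_for_auc(auc, sigma_u2, beta0 = beta0,
                                     mc_n = mc_n, seed = seed)
    beta0 <- calibrate_intercept_for_rate(event_rate, beta1, sigma_u2,
                                          mc_n = mc_n, seed = seed + 1)
  }
  structure(list(icc_target = icc, auc_target = auc,
                 event_rate_target = event_rate, n_clusters = n_clusters,
                 n_per_cluster = n_per_cluster, beta0 = beta0, beta1 = beta1,
                 beta2 = 0, nonlinearity = "none", sigma_u2 = sigma_u2,
                 seed = seed), class = "superpopulation_spec")
}

#' @export
print.superpopulation_spec <- function(x, ...) {
  cat("<superpopulation_spec> ICC=", x$icc_target, ", AUC=", x$auc_target,
      ", rate=", x$event_rate_target, "; beta0=", signif(x$beta0, 4),
      ", beta1=", signif(x$beta1, 4), ", sigma_u2=", signif(x$sigma_u2, 4),
      "\n", sep = "")
  invisible(x)
}

true_logit <- function(spec, x, u) {
  nl <- switch(spec$nonlinearity,
               none = 0,
               quadratic = spec$beta2 * x^2,
               step_mix = spec$beta2 * (2 * expit(4 * x) - 1))
  spec$beta0 + spec$beta1 * x + nl + u
}

#' Generate a clustered superpopulation
#'
#' Realises the data-generating model of a [superpopulation_spec()]: one
#' normal random intercept per cluster, a standard-normal linear predictor
#' per individual, true probabilities through the logistic link and
#' Bernoulli outcomes. Fully reproducible from the seed.
#'
#' @param spec A `superpopulation_spec`.
#' @param seed Integer seed for the generation step (defaults to
#'   `spec$seed`).
#' @return A `superpopulation` list: `spec`, `u` (named vector of realised
#'   cluster intercepts) and `data` (tibble with `cluster`, `x`, `true_p`,
#'   `y`).
#' @export
make_superpopulation <- function(spec, seed = spec$seed) {
  stopifnot(inherits(spec, "superpopulation_spec"))
  J <- spec$n_clusters
  n <- spec$n_per_cluster
  labels <- sprintf("C%03d", seq_len(J))
  gen <- function() {
    u <- stats::rnorm(J, sd = sqrt(spec$sigma_u2))
    names(u) <- labels
    x <- stats::rnorm(J * n)
    cl <- rep(labels, each = n)
    tp <- expit(true_logit(spec, x, u[cl]))
    y <- as.integer(stats::runif(J * n) < tp)
    list(u = u,
         data = tibble::tibble(cluster = cl, x = x, true_p = tp, y = y))
  }
  out <- withr::with_seed(seed, gen())
  structure(list(spec = spec, u = out$u, data = out$data),
            class = "superpopulation")
}

#' @export
print.superpopulation <- function(x, ...) {
  cat("<superpopulation> ", nrow(x$data), " rows in ", length(x$u),
      " clusters; event rate ", sprintf("%.4f", mean(x$data$y)), "\n",
      sep = "")
  invisible(x)
}

#' Generate a superpopulation with a non-linear truth
#'
#' Variant generator whose true logit risk is non-linear in the predictor
#' (`quadratic`: adds `beta2 * x^2`; `step_mix`: adds a smoothed step
#' `beta2 * (2 expit(4 x) - 1)`), used to exercise the flexibility of the
#' smoothers beyond the logistic-linear design. The intercept is
#' recalibrated by Monte-Carlo root-finding so the marginal event rate
#' still hits the target recorded in `spec`.
#'
#' @inheritParams make_superpopulation
#' @param nonlinearity `"quadratic"` or `"step_mix"`.
#' @param beta2 Magnitude of the non-linear term.
#' @param mc_n Monte-Carlo size for the intercept recalibration.
#' @return A `superpopulation`; its `spec` carries the updated `beta0`,
#'   `beta2` and `nonlinearity`.
#' @export
make_nonlinear_superpopulation <- function(spec,
                                           nonlinearity = c("quadratic",
                                                            "step_mix"),
                                           beta2 = 0.5, mc_n = 500000,
                                           seed = spec$seed) {
  stopifnot(inherits(spec, "superpopulation_spec"))
  nonlinearity <- match.arg(nonlinearity)
  spec$nonlinearity <- nonlinearity
  spec$beta2 <- beta2
  d <- mc_draws(mc_n, spec$sigma_u2, spec$seed)
  f <- function(b0) {
    s <- spec
    s$beta0 <- b0
    mean(expit(true_logit(s, d$x, d$u))) - spec$event_rate_target
  }
  spec$beta0 <- stats::uniroot(f, c(-15, 15), tol = 1e-7)$root
  make_superpopulation(spec, seed = seed)
}

#' Draw a development/validation scenario from a superpopulation
#'
#' Samples `n_clusters` clusters without replacement, then from each
#' sampled cluster j takes `n_j = ceiling(epc * 1.15 / prev_j)` rows
#' without replacement, where `prev_j` is the cluster's realised prevalence
#' in the superpopulation — so the expected number of events per cluster is
#' at least `epc`.
#'
#' @param sp A `superpopulation`.
#' @param n_clusters Number of clusters to sample (e.g. 5 or 30).
#' @param epc Target events per cluster (e.g. 20 or 200).
#' @param seed Integer seed.
#' @param exclude Cluster labels not eligible for sampling.
#' @return A tibble with columns `cluster`, `x`, `true_p`, `y`.
#' @export
draw_scenario <- function(sp, n_clusters, epc, seed, exclude = character(0)) {
  stopifnot(inherits(sp, "superpopulation"))
  pool <- setdiff(names(sp$u), exclude)
  if (n_clusters > length(pool)) {
    stop("requested more clusters than available", call. = FALSE)
  }
  withr::with_seed(seed, {
    picked <- sample(pool, n_clusters)
    parts <- lapply(picked, function(cl) {
      rows <- sp$data[sp$data$cluster == cl, ]
      prev <- mean(rows$y)
      n_j <- ceiling(epc * 1.15 / prev)
      if (n_j > nrow(rows)) {
        stop("cluster ", cl, " too small for epc = ", epc, call. = FALSE)
      }
      rows[sample(nrow(rows), n_j), ]
    })
    dplyr::bind_rows(parts)
  })
}

#' Sample a large validation set across clusters
#'
#' Draws `n_total` rows uniformly from `n_clusters` randomly selected
#' clusters, the "ideal validation" companion of [draw_scenario()].
#'
#' @inheritParams draw_scenario
#' @param n_total Total number of rows to draw.
#' @export
draw_validation <- function(sp, n_clusters = 30, n_total = 100000, seed = 1,
                            exclude = character(0)) {
  stopifnot(inherits(sp, "superpopulation"))
  pool <- setdiff(names(sp$u), exclude)
  if (n_clusters > length(pool)) {
    stop("requested more clusters than available", call. = FALSE)
  }
  withr::with_seed(seed, {
    picked <- sample(pool, n_clusters)
    rows <- sp$data[sp$data$cluster %in% picked, ]
    rows[sample(nrow(rows), min(n_total, nrow(rows))), ]
  })
}

#' Train a pooled spline prediction model
#'
#' Fits a cluster-ignorant logistic regression of the outcome on a
#' restricted cubic spline (3 knots) of the predictor — the hypothetical
#' prediction model whose calibration the clustered methods then assess.
#'
#' @param sample A tibble with columns `x` and `y` (e.g. from
#'   [draw_scenario()]).
#' @return A `risk_predictor` object mapping `x` to a predicted risk.
#' @export
train_prediction_model <- function(sample) {
  stopifnot(all(c("x", "y") %in% names(sample)))
  if (length(unique(sample$y)) < 2) {
    stop("training sample needs both outcome classes", call. = FALSE)
  }
  kn <- place_knots(sample$x, 3)
  fit <- fit_logistic(sample$y, cbind(1, rcs_basis(sample$x, kn)),
                      kind = "logistic_rcs", knots = kn)
  structure(list(model = fit, knots = kn, x_range = range(sample$x)),
            class = "risk_predictor")
}

#' @export
predict.risk_predictor <- function(object, newdata, ...) {
  x <- if (is.data.frame(newdata)) newdata$x else newdata
  Xg <- cbind(1, rcs_basis(x, object$knots))
  clip_prob(expit(drop(Xg %*% object$model$coefficients)))
}

#' @export
print.risk_predictor <- function(x, ...) {
  cat("<risk_predictor> logistic RCS(3), trained on n=", x$model$n_obs,
      "\n", sep = "")
  invisible(x)
}

#' Attach predicted risks to a drawn sample
#'
#' @param sample A tibble with column `x`.
#' @param predictor A `risk_predictor`.
#' @return A `clustered_predictions` tibble (`cluster`, `y`, `p`) carrying
#'   the sample's remaining columns.
#' @export
apply_predictor <- function(sample, predictor) {
  sample$p <- predict(predictor, sample)
  suppressWarnings(
    as_clustered_predictions(sample[, c("cluster", "y", "p")]))
}

#' True calibration curve of a predictor in a given cluster
#'
#' For each predicted risk on the grid, numerically inverts the (monotone)
#' prediction model to the underlying predictor value and evaluates the
#' true event probability of the data-generating model at that value, with
#' the cluster deviation `u` (0 for the average cluster). If the predictor
#' is not monotone on the probed lattice, falls back to a large-sample
#' empirical estimate: the mean true risk among superpopulation rows whose
#' prediction falls within 0.005 of the grid point.
#'
#' @param spec A `superpopulation_spec`.
#' @param predictor A `risk_predictor`.
#' @param grid Predicted-risk grid.
#' @param u Cluster random intercept (scalar).
#' @param sp Optional `superpopulation`, required for the non-monotone
#'   fallback.
#' @return Numeric vector of true observed proportions (NA where the grid
#'   point is outside the predictor's attainable range).
#' @export
true_curve <- function(spec, predictor, grid, u = 0, sp = NULL) {
  xs <- true_curve_x(predictor, grid, sp = sp)
  if (xs$monotone) expit(true_logit(spec, xs$x, u)) else xs$empirical
}

# Shared inversion step: map grid probabilities back to predictor values.
true_curve_x <- function(predictor, grid, sp = NULL) {
  lattice <- seq(-8, 8, length.out = 1000)
  pl <- predict(predictor, lattice)
  monotone <- all(diff(pl) > 0)
  x <- rep(NA_real_, length(grid))
  empirical <- rep(NA_real_, length(grid))
  if (monotone) {
    for (i in seq_along(grid)) {
      if (grid[i] < min(pl) || grid[i] > max(pl)) next
      x[i] <- stats::uniroot(function(z) predict(predictor, z) - grid[i],
                             range(lattice), tol = 1e-6)$root
    }
  } else {
    if (is.null(sp)) {
      stop("predictor not monotone; supply `sp` for the empirical fallback",
           call. = FALSE)
    }
    message("predictor not monotone on the lattice; using empirical truth")
    phat <- predict(predictor, sp$data$x)
    for (i in seq_along(grid)) {
      w <- abs(phat - grid[i]) <= 0.005
      if (any(w)) empirical[i] <- mean(sp$data$true_p[w])
    }
  }
  list(x = x, empirical = empirical, monotone = monotone)
}

#' Estimate the ICC of clustered risk data
#'
#' Applies the latent-scale ICC formula
#' `sigma_u2 / (sigma_u2 + pi^2 / 3)` to the between-cluster variance of a
#' null random-intercept model. With `from = "risk"` (the default when a
#' risk column is present) the null model is a linear mixed model of the
#' logit risk, which recovers the design ICC of the data-generating model
#' regardless of how strong the individual-level predictor is. With
#' `from = "outcome"` a null logistic model is fitted to the binary
#' outcomes instead; note that its cluster variance is attenuated towards 0
#' when individual-level discrimination is high, so it understates the
#' latent ICC in high-AUC settings.
#'
#' @param data A data frame with a `cluster` column plus `true_p`/`p`
#'   (risk route) or `y` (outcome route).
#' @param from `"auto"` (risk if available), `"risk"` or `"outcome"`.
#' @return The estimated intraclass correlation.
#' @export
estimate_icc <- function(data, from = c("auto", "risk", "outcome")) {
  from <- match.arg(from)
  risk_col <- intersect(c("true_p", "p"), names(data))[1]
  if (from == "auto") {
    from <- if (!is.na(risk_col)) "risk" else "outcome"
  }
  cl <- factor(data$cluster)
  if (from == "risk") {
    if (is.na(risk_col)) stop("no risk column for from = \"risk\"",
                              call. = FALSE)
    lr <- logit(clip_prob(data[[risk_col]]))
    fit <- lme4::lmer(lr ~ 1 + (1 | cluster),
                      data = data.frame(lr = lr, cluster = cl))
    s2 <- as.numeric(lme4::VarCorr(fit)$cluster)
  } else {
    fit <- lme4::glmer(y ~ 1 + (1 | cluster),
                       data = data.frame(y = data$y, cluster = cl),
                       family = stats::binomial())
    s2 <- as.numeric(lme4::VarCorr(fit)$cluster)
  }
  variance_to_icc(s2)
}
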