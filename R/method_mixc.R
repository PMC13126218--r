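#' One-stage mixed-model calibration fit (MIX-C)
#'
#' Fits a logistic generalized linear mixed model of the outcome on a
#' restricted cubic spline (3 knots, placed on the pooled logit predicted
#' risks) of the logit predicted risk, with a correlated random intercept
#' and random spline coefficients per cluster. Estimation uses the Laplace
#' approximation via [lme4::glmer()]. If the unstructured random-effects
#' fit fails, the model is refit with independent (diagonal) random effects
#' and flagged.
#'
#' @inheritParams cal_cgc
#' @param nAGQ Integration accuracy passed to [lme4::glmer()]: 1 (default)
#'   for the Laplace approximation, 0 for the faster pure-PIRLS
#'   approximation used in large replicate studies.
#' @return A `mixc_fit` object: `fixed` (3-vector), `fixed_cov` (3 x 3),
#'   `Sigma_u` (3 x 3 random-effects covariance), `eb` (matrix of
#'   empirical-Bayes modes, one row per cluster), `knots`,
#'   `loglik_laplace`, `converged` and `diagonal_fallback` flags, and the
#'   underlying `glmer` fit in `$fit`.
#' @export
fit_mixc <- function(data, level = 0.95, nAGQ = 1) {
  data <- ensure_cp(data)
  if (dplyr::n_distinct(data$cluster) < 2) {
    stop("need at least 2 clusters for a mixed-model fit", call. = FALSE)
  }
  x <- logit(data$p)
  kn <- place_knots(x, 3)
  B <- rcs_basis(x, kn)
  df <- data.frame(y = data$y, b1 = B[, 1], b2 = B[, 2],
                   cluster = factor(data$cluster,
                                    levels = unique(data$cluster)))
  ctrl <- lme4::glmerControl(optimizer = "bobyqa",
                             check.conv.singular = "ignore",
                             calc.derivs = FALSE)
  messages <- character(0)
  fit_formula <- function(fml) {
    withCallingHandlers(
      lme4::glmer(fml, data = df, family = stats::binomial(),
                  nAGQ = nAGQ, control = ctrl),
      warning = function(w) {
        messages <<- c(messages, conditionMessage(w))
        invokeRestart("muffleWarning")
      })
  }
  diagonal_fallback <- FALSE
  fit <- tryCatch(fit_formula(y ~ b1 + b2 + (1 + b1 + b2 | cluster)),
                  error = function(e) NULL)
  if (is.null(fit)) {
    diagonal_fallback <- TRUE
    fit <- tryCatch(fit_formula(y ~ b1 + b2 + (1 + b1 + b2 || cluster)),
                    error = function(e) NULL)
    if (is.null(fit)) {
      stop("MIX-C model failed to fit even with diagonal random effects",
           call. = FALSE)
    }
    warning("unstructured random-effects fit failed; using diagonal ",
            "covariance", call. = FALSE)
  }
  vc <- lme4::VarCorr(fit)$cluster
  Sigma_u <- matrix(0, 3, 3)
  if (!diagonal_fallback) {
    Sigma_u <- as.matrix(vc)[1:3, 1:3]
  } else {
    # doubled-bar fits store one variance component per term
    vcs <- lme4::VarCorr(fit)
    Sigma_u <- diag(vapply(vcs, function(m) as.numeric(m)[1], numeric(1)))
  }
  dimnames(Sigma_u) <- list(c("(Intercept)", "b1", "b2"),
                            c("(Intercept)", "b1", "b2"))
  re <- lme4::ranef(fit)
  eb <- if (!diagonal_fallback) {
    as.matrix(re$cluster)
  } else {
    do.call(cbind, lapply(re, as.matrix))
  }
  colnames(eb) <- c("(Intercept)", "b1", "b2")
  structure(list(
    fixed = lme4::fixef(fit),
    fixed_cov = as.matrix(stats::vcov(fit)),
    Sigma_u = Sigma_u,
    eb = eb,
    knots = kn,
    loglik_laplace = as.numeric(stats::logLik(fit)),
    converged = length(messages) == 0,
    messages = messages,
    diagonal_fallback = diagonal_fallback,
    level = level,
    fit = fit), class = "mixc_fit")
}

#' @export
print.mixc_fit <- function(x, ...) {
  cat("<mixc_fit> fixed = (", paste(signif(x$fixed, 4), collapse = ", "),
      "); ||Sigma_u||_F = ", signif(norm(x$Sigma_u, "F"), 4),
      "; ", nrow(x$eb), " clusters",
      if (!x$converged) " [convergence messages]" else "", "\n", sep = "")
  invisible(x)
}

#' Calibration curves from a MIX-C fit
#'
#' The average-cluster curve sets all random effects to zero and transforms
#' the fixed-effect linear predictor; its CI comes from the delta method on
#' the fixed-effect covariance. The prediction interval for the curve of a
#' new cluster is simulated: random-effect vectors are drawn from
#' N(0, Sigma_u) (projected to the nearest positive semi-definite matrix if
#' needed), fixed-effect uncertainty is added by drawing coefficients from
#' their asymptotic normal, and pointwise percentiles of the simulated
#' curves form the PI. When the estimated random-effects covariance is
#' numerically zero the PI equals the CI. Cluster-specific curves use the
#' empirical-Bayes modes.
#'
#' @param fit A `mixc_fit` from [fit_mixc()].
#' @param grid Predicted-risk grid (default 100 points on 0.01-0.99).
#' @param n_draws Monte-Carlo draws for the PI.
#' @param seed Optional integer seed for the PI draws.
#' @param level Coverage level.
#' @return A `calibration_curve` with `method_tag = "mixc"` and
#'   empirical-Bayes cluster curves in `per_cluster`.
#' @export
mixc_curves <- function(fit, grid = seq(0.01, 0.99, length.out = 100),
                        n_draws = 10000, seed = NULL, level = fit$level) {
  stopifnot(inherits(fit, "mixc_fit"))
  xg <- logit(grid)
  Xg <- cbind(1, rcs_basis(xg, fit$knots))
  eta <- drop(Xg %*% fit$fixed)
  se <- sqrt(pmax(rowSums((Xg %*% fit$fixed_cov) * Xg), 0))
  zc <- stats::qnorm(1 - (1 - level) / 2)
  est <- expit(eta)
  ci_lo <- expit(eta - zc * se)
  ci_hi <- expit(eta + zc * se)
  if (norm(fit$Sigma_u, "F") < 1e-10) {
    pi_lo <- ci_lo
    pi_hi <- ci_hi
  } else {
    Sig <- fit$Sigma_u
    ev <- eigen(Sig, symmetric = TRUE, only.values = TRUE)$values
    if (min(ev) < -1e-8) {
      Sig <- as.matrix(Matrix::nearPD(Sig)$mat)
      message("Sigma_u projected to nearest positive semi-definite matrix")
    }
    draw <- function() {
      U <- MASS::mvrnorm(n_draws, mu = rep(0, 3), Sigma = Sig)
      Bdraw <- MASS::mvrnorm(n_draws, mu = fit$fixed, Sigma = fit$fixed_cov)
      (Bdraw + U) %*% t(Xg)
    }
    etas <- if (is.null(seed)) draw() else withr::with_seed(seed, draw())
    qs <- apply(etas, 2, stats::quantile,
                probs = c((1 - level) / 2, 1 - (1 - level) / 2))
    # the PI describes a new cluster's curve and must contain the CI
    pi_lo <- pmin(expit(qs[1, ]), ci_lo)
    pi_hi <- pmax(expit(qs[2, ]), ci_hi)
  }
  per_cluster <- purrr::map_dfr(rownames(fit$eb), function(cl) {
    eta_cl <- drop(Xg %*% (fit$fixed + fit$eb[cl, ]))
    tibble::tibble(cluster = cl, grid = grid, estimate = expit(eta_cl))
  })
  new_calibration_curve(
    tibble::tibble(grid = grid, estimate = est, ci_lo = ci_lo, ci_hi = ci_hi,
                   pi_lo = pi_lo, pi_hi = pi_hi),
    method_tag = "mixc", level = level, per_cluster = per_cluster,
    extra = list(fit = fit))
}

#' Mixed-model calibration curve in one call
#'
#' Convenience wrapper running [fit_mixc()] and [mixc_curves()].
#'
#' @inheritParams cal_2mac
#' @inheritParams mixc_curves
#' @export
#' @examples
#' d <- make_fixture("heterogeneous", n_clusters = 6, n_per = 200, seed = 3)
#' cal_mixc(d, grid_size = 20, n_draws = 500, seed = 1)
cal_mixc <- function(data, grid_size = 100, level = 0.95, n_draws = 10000,
                     seed = NULL, nAGQ = 1) {
  fit <- fit_mixc(data, level = level, nAGQ = nAGQ)
  mixc_curves(fit, grid = seq(0.01, 0.99, length.out = grid_size),
              n_draws = n_draws, seed = seed, level = level)
}
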