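#' Logit and inverse-logit links
#'
#' @param p Probabilities strictly inside (0, 1).
#' @param x Real values.
#' @return `logit()` returns log(p / (1 - p)); `expit()` its inverse.
#' @export
logit <- function(p) {
  if (any(!is.finite(p) | p <= 0 | p >= 1)) {
    stop("logit() requires probabilities strictly inside (0, 1)",
         call. = FALSE)
  }
  stats::qlogis(p)
}

#' @rdname logit
#' @export
expit <- function(x) stats::plogis(x)

clip_prob <- function(p, eps = 1e-5) pmin(pmax(p, eps), 1 - eps)

#' Place restricted-cubic-spline knots at conventional quantiles
#'
#' Uses the Harrell default placement: 3 knots at the 0.10/0.50/0.90
#' empirical quantiles, 4 at 0.05/0.35/0.65/0.95 and 5 at
#' 0.05/0.275/0.50/0.725/0.95.
#'
#' @param x Numeric vector of predictor values.
#' @param k Number of knots, one of 3, 4, 5.
#' @return Strictly increasing numeric vector of `k` knots.
#' @export
place_knots <- function(x, k = 3) {
  stopifnot(k %in% c(3, 4, 5))
  x <- x[is.finite(x)]
  if (length(unique(x)) < k) {
    stop("need at least ", k, " distinct values to place ", k, " knots",
         call. = FALSE)
  }
  probs <- switch(as.character(k),
                  "3" = c(0.10, 0.50, 0.90),
                  "4" = c(0.05, 0.35, 0.65, 0.95),
                  "5" = c(0.05, 0.275, 0.50, 0.725, 0.95))
  kn <- unname(stats::quantile(x, probs, type = 7))
  if (any(diff(kn) <= 0)) {
    stop("knot placement produced ties; too few distinct values",
         call. = FALSE)
  }
  kn
}

#' Restricted cubic spline basis (Harrell construction)
#'
#' Builds the k-1 column basis for a restricted cubic spline with the given
#' knots: the linear term plus k-2 truncated-cubic terms constrained to be
#' linear beyond the outer knots, normalised by the squared knot range.
#'
#' @param x Numeric vector.
#' @param knots Strictly increasing knot vector (length 3 to 5).
#' @return Numeric matrix with `length(x)` rows and `length(knots) - 1`
#'   columns; the first column is `x` itself.
#' @export
rcs_basis <- function(x, knots) {
  k <- length(knots)
  stopifnot(k >= 3)
  if (any(diff(knots) <= 0)) {
    stop("knots must be strictly increasing", call. = FALSE)
  }
  norm2 <- (knots[k] - knots[1])^2
  cube <- function(u) pmax(u, 0)^3
  B <- matrix(0, length(x), k - 1)
  B[, 1] <- x
  for (j in seq_len(k - 2)) {
    B[, j + 1] <- (cube(x - knots[j]) -
      cube(x - knots[k - 1]) * (knots[k] - knots[j]) /
        (knots[k] - knots[k - 1]) +
      cube(x - knots[k]) * (knots[k - 1] - knots[j]) /
        (knots[k] - knots[k - 1])) / norm2
  }
  colnames(B) <- c("x", paste0("rcs", seq_len(k - 2)))
  B
}

#' Maximum-likelihood logistic regression with a separation guard
#'
#' Fits a binomial GLM of `y` on the columns of `X` (which must include any
#' intercept column). When the fit shows signs of complete separation
#' (non-convergence or coefficients beyond 20 in absolute value), the model
#' is refit by ridge-penalised IRLS with a light penalty on non-intercept
#' terms and a warning is emitted, so that downstream two-stage pipelines
#' keep running on sparse clusters.
#'
#' @param y Binary 0/1 response.
#' @param X Design matrix (n x p), full column rank, first column treated as
#'   the intercept for penalisation purposes.
#' @param kind Label stored on the result (`"logistic_linear"` or
#'   `"logistic_rcs"`).
#' @param knots Optional knot vector stored alongside spline fits.
#' @return A `fitted_curve_model` list: coefficients, covariance, log
#'   likelihood, number of observations and the range of the fitted
#'   predictor.
#' @export
fit_logistic <- function(y, X, kind = "logistic_linear", knots = NULL) {
  X <- as.matrix(X)
  stopifnot(length(y) == nrow(X), all(y %in% c(0, 1)))
  if (nrow(X) < ncol(X) + 1) stop("too few observations", call. = FALSE)
  if (qr(X)$rank < ncol(X)) stop("design matrix is rank deficient",
                                 call. = FALSE)
  fit <- suppressWarnings(
    stats::glm.fit(X, y, family = stats::binomial(),
                   control = stats::glm.control(epsilon = 1e-10,
                                                maxit = 100)))
  beta <- fit$coefficients
  separated <- !fit$converged || any(abs(beta) > 20)
  if (separated) {
    warning("possible separation; refitting with a small ridge penalty",
            call. = FALSE)
    rf <- ridge_irls(y, X, lambda = 1e-4)
    beta <- rf$beta
    cov <- rf$cov
    ll <- rf$loglik
  } else {
    eta <- drop(X %*% beta)
    mu <- expit(eta)
    W <- mu * (1 - mu)
    info <- crossprod(X, X * W)
    cov <- solve(info)
    ll <- sum(y * eta - log1p(exp(eta)))
  }
  new_fitted_curve_model(kind = kind, coefficients = beta, coef_cov = cov,
                         knots = knots, loglik = ll, n_obs = length(y),
                         x_range = range(X[, min(2, ncol(X))]),
                         separated = separated)
}

# Ridge-penalised IRLS; the intercept (column 1) is left unpenalised.
ridge_irls <- function(y, X, lambda = 1e-4, maxit = 100, tol = 1e-8) {
  p <- ncol(X)
  pen <- diag(c(0, rep(lambda, p - 1)), p)
  beta <- rep(0, p)
  for (it in seq_len(maxit)) {
    eta <- drop(X %*% beta)
    mu <- expit(eta)
    W <- pmax(mu * (1 - mu), 1e-10)
    grad <- crossprod(X, y - mu) - pen %*% beta
    H <- crossprod(X, X * W) + pen
    step <- solve(H, grad)
    beta <- beta + drop(step)
    if (sqrt(sum(grad^2)) < tol) break
  }
  eta <- drop(X %*% beta)
  list(beta = beta, cov = solve(H),
       loglik = sum(y * eta - log1p(exp(eta))))
}

new_fitted_curve_model <- function(kind, coefficients = NULL, coef_cov = NULL,
                                   knots = NULL, span = NULL, loglik = NA_real_,
                                   n_obs = NA_integer_, x_range = c(NA, NA),
                                   fit = NULL, aicc = NA_real_,
                                   separated = FALSE) {
  structure(list(kind = kind, coefficients = coefficients,
                 coef_cov = coef_cov, knots = knots, span = span,
                 loglik = loglik, n_obs = n_obs, x_range = x_range,
                 fit = fit, aicc = aicc, separated = separated),
            class = "fitted_curve_model")
}

#' @export
print.fitted_curve_model <- function(x, ...) {
  cat("<fitted_curve_model> kind=", x$kind, ", n=", x$n_obs, sep = "")
  if (!is.null(x$knots)) cat(", knots=", length(x$knots), sep = "")
  if (!is.null(x$span)) cat(", span=", x$span, sep = "")
  cat("\n")
  invisible(x)
}

n_params <- function(m) length(m$coefficients)

#' Select the number of spline knots by sequential deviance tests
#'
#' Fits logistic calibration models with restricted cubic splines on 3, 4
#' and 5 knots and keeps the smallest number of knots that no larger
#' candidate improves upon at the 5% level, comparing deviance differences
#' against a chi-squared reference with degrees of freedom equal to the
#' difference in parameter count (comparisons 3-4, 3-5 and 4-5). When too
#' few distinct predictor values exist for 5 (or 4) knots the candidate set
#' shrinks accordingly.
#'
#' @param y Binary response.
#' @param x Numeric predictor (typically logit of the predicted risk).
#' @param alpha Test size for the deviance comparisons.
#' @return The selected `fitted_curve_model` (kind `"logistic_rcs"`).
#' @export
select_rcs_knots <- function(y, x, alpha = 0.05) {
  ks <- c(3, 4, 5)
  ks <- ks[ks <= length(unique(x))]
  ks <- ks[(length(y) >= ks)]
  if (length(ks) == 0) stop("too few distinct values for a spline fit",
                            call. = FALSE)
  fits <- lapply(ks, function(k) {
    kn <- place_knots(x, k)
    fit_logistic(y, cbind(1, rcs_basis(x, kn)), kind = "logistic_rcs",
                 knots = kn)
  })
  names(fits) <- as.character(ks)
  better <- function(small, big) {
    d <- 2 * (fits[[as.character(big)]]$loglik -
                fits[[as.character(small)]]$loglik)
    df <- n_params(fits[[as.character(big)]]) -
      n_params(fits[[as.character(small)]])
    stats::pchisq(max(d, 0), df, lower.tail = FALSE) < alpha
  }
  for (k in ks) {
    larger <- ks[ks > k]
    if (!any(vapply(larger, function(b) better(k, b), logical(1)))) {
      return(fits[[as.character(k)]])
    }
  }
  fits[[as.character(max(ks))]]
}

#' LOESS smoother with bias-corrected AIC
#'
#' Fits a local quadratic regression of the raw 0/1 outcome on the logit of
#' the predicted risk with tricube weights, and scores it with the
#' bias-corrected AIC for linear smoothers,
#' `AICc = n log(sigma2) + n (n + tr L) / (n - tr L - 2)`,
#' where `L` is the smoother matrix and `sigma2` the mean squared residual.
#'
#' @param y Binary response.
#' @param x Numeric predictor.
#' @param span LOESS span in (0, 1].
#' @param degree Local polynomial degree.
#' @return A `fitted_curve_model` of kind `"loess"`; the AICc is stored in
#'   `$aicc`.
#' @export
fit_loess <- function(y, x, span, degree = 2) {
  stopifnot(length(y) >= 10, span > 0, span <= 1)
  th <- if (length(y) <= 1500) "exact" else "approximate"
  dat <- data.frame(x = x, y = y)
  fit <- suppressWarnings(stats::loess(
    y ~ x, data = dat, span = span, degree = degree, family = "gaussian",
    control = stats::loess.control(surface = "direct",
                                   statistics = "approximate",
                                   trace.hat = th)))
  n <- length(y)
  tr <- fit$trace.hat
  sigma2 <- mean(stats::residuals(fit)^2)
  aicc <- if (n - tr - 2 > 0) {
    n * log(sigma2) + n * (n + tr) / (n - tr - 2)
  } else {
    Inf
  }
  new_fitted_curve_model(kind = "loess", span = span, loglik = NA_real_,
                         n_obs = n, x_range = range(x), fit = fit,
                         aicc = aicc)
}

#' @rdname fit_loess
#' @param spans Candidate span grid; the span minimising AICc is returned.
#' @export
select_span <- function(y, x, spans = seq(0.3, 1, by = 0.1)) {
  scores <- vapply(spans, function(s) {
    tryCatch(fit_loess(y, x, s)$aicc, error = function(e) Inf)
  }, numeric(1))
  if (all(!is.finite(scores))) {
    stop("all candidate spans failed", call. = FALSE)
  }
  spans[which.min(scores)]
}

#' Predict observed proportions on a risk grid
#'
#' Evaluates a fitted calibration model at the logit of a grid of predicted
#' risks and returns the estimated observed proportion together with a
#' delta-method standard error on the logit scale. For LOESS the pointwise
#' standard error of the linear smoother is transformed to the logit scale.
#'
#' @param model A `fitted_curve_model`.
#' @param grid Predicted-risk values in (0, 1).
#' @return A tibble with columns `grid`, `estimate` and `se_logit`.
#' @export
predict_observed_proportion <- function(model, grid) {
  stopifnot(inherits(model, "fitted_curve_model"))
  if (any(grid <= 0 | grid >= 1)) {
    stop("grid values must lie strictly inside (0, 1)", call. = FALSE)
  }
  xg <- logit(grid)
  if (model$kind %in% c("logistic_linear", "logistic_rcs")) {
    Xg <- if (model$kind == "logistic_rcs") {
      cbind(1, rcs_basis(xg, model$knots))
    } else {
      cbind(1, xg)
    }
    eta <- drop(Xg %*% model$coefficients)
    se <- sqrt(pmax(rowSums((Xg %*% model$coef_cov) * Xg), 0))
    tibble::tibble(grid = grid, estimate = expit(eta), se_logit = se)
  } else if (model$kind == "loess") {
    pr <- stats::predict(model$fit, newdata = data.frame(x = xg), se = TRUE)
    est <- clip_prob(pr$fit)
    se_logit <- pr$se.fit / (est * (1 - est))
    tibble::tibble(grid = grid, estimate = est, se_logit = se_logit)
  } else {
    stop("unknown model kind: ", model$kind, call. = FALSE)
  }
}
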