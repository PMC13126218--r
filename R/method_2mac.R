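#' Fit a flexible calibration curve per cluster
#'
#' Stage 1 of the two-stage meta-analysis approach: each cluster gets its
#' own smooth calibration model of the outcome on the logit predicted risk,
#' either a restricted cubic spline logistic model with the number of knots
#' chosen by deviance tests ([select_rcs_knots()]), or a LOESS smoother with
#' the span chosen by bias-corrected AIC ([select_span()]). Clusters with
#' fewer than 10 observations or a single outcome class cannot support a
#' smooth fit and are excluded with a warning.
#'
#' @inheritParams cal_cgc
#' @param smoother `"rcs"` or `"loess"`.
#' @return A named list of `fitted_curve_model`s, one per retained cluster.
#' @export
fit_cluster_curves <- function(data, smoother = c("rcs", "loess")) {
  data <- ensure_cp(data)
  smoother <- match.arg(smoother)
  fits <- list()
  for (cl in unique(data$cluster)) {
    rows <- data[data$cluster == cl, ]
    if (nrow(rows) < 10 || length(unique(rows$y)) < 2) {
      warning("cluster ", cl, " excluded: needs >= 10 observations and both ",
              "outcome classes", call. = FALSE)
      next
    }
    x <- logit(rows$p)
    fit <- tryCatch({
      if (smoother == "rcs") {
        select_rcs_knots(rows$y, x)
      } else {
        sp <- select_span(rows$y, x)
        fit_loess(rows$y, x, sp)
      }
    }, error = function(e) {
      warning("cluster ", cl, " excluded: ", conditionMessage(e),
              call. = FALSE)
      NULL
    })
    if (!is.null(fit)) fits[[cl]] <- fit
  }
  if (length(fits) == 0) {
    stop("all clusters were excluded in stage 1", call. = FALSE)
  }
  fits
}

#' Two-stage meta-analysis calibration (2MA-C)
#'
#' Estimates the average-cluster flexible calibration curve in two stages:
#' cluster-specific smoothers ([fit_cluster_curves()]) are evaluated on a
#' fixed grid of predicted risks from 0.01 to 0.99, and at every grid point
#' the logit-scale cluster estimates are combined with a univariate
#' random-effects meta-analysis ([meta_uni()]) weighting clusters by the
#' inverse of their within-cluster (delta-method) variance plus the
#' between-cluster variance. The pooled mean, z-based CI and t-based PI are
#' back-transformed to the probability scale. Each point in the grid is
#' pooled independently.
#'
#' @inheritParams fit_cluster_curves
#' @param grid_size Number of evenly spaced grid points between 0.01 and
#'   0.99 (default 100).
#' @param level Coverage level.
#' @param restrict_range If `TRUE`, each cluster only contributes to grid
#'   points inside its own observed logit-risk range (no tail
#'   extrapolation); default `FALSE`, i.e. every cluster is evaluated on the
#'   full grid.
#' @param method tau^2 estimator passed to [meta_uni()].
#' @return A `calibration_curve` (`method_tag` `"2mac_rcs"` or
#'   `"2mac_loess"`) with cluster-specific stage-1 curves in the
#'   `per_cluster` attribute and the pointwise tau^2 estimates as a `tau2`
#'   column.
#' @export
#' @examples
#' d <- make_fixture("heterogeneous", n_clusters = 8, n_per = 150, seed = 2)
#' cal_2mac(d, grid_size = 25)
cal_2mac <- function(data, smoother = c("rcs", "loess"), grid_size = 100,
                     level = 0.95, restrict_range = FALSE,
                     method = "REML") {
  data <- ensure_cp(data)
  smoother <- match.arg(smoother)
  fits <- fit_cluster_curves(data, smoother)
  if (length(fits) < 2) {
    stop("need at least 2 clusters surviving stage 1", call. = FALSE)
  }
  grid <- seq(0.01, 0.99, length.out = grid_size)
  preds <- purrr::map(fits, predict_observed_proportion, grid = grid)
  theta <- vapply(preds, function(d) logit(clip_prob(d$estimate)),
                  numeric(grid_size))
  v <- vapply(preds, function(d) pmax(d$se_logit^2, 1e-10),
              numeric(grid_size))
  if (restrict_range) {
    xg <- logit(grid)
    for (j in seq_along(fits)) {
      out <- xg < fits[[j]]$x_range[1] | xg > fits[[j]]$x_range[2]
      theta[out, j] <- NA_real_
    }
  }
  est <- ci_lo <- ci_hi <- pi_lo <- pi_hi <- tau2 <- rep(NA_real_, grid_size)
  for (i in seq_len(grid_size)) {
    ok <- is.finite(theta[i, ]) & is.finite(v[i, ])
    if (sum(ok) < 2) next
    mf <- tryCatch(meta_uni(theta[i, ok], v[i, ok], method = method,
                            level = level),
                   error = function(e) NULL)
    if (is.null(mf)) {
      # fixed-effect inverse-variance mean, intervals left missing
      w <- 1 / v[i, ok]
      est[i] <- expit(sum(w * theta[i, ok]) / sum(w))
      next
    }
    est[i] <- expit(mf$mu)
    ci_lo[i] <- expit(mf$ci[1]); ci_hi[i] <- expit(mf$ci[2])
    pi_lo[i] <- expit(mf$pi[1]); pi_hi[i] <- expit(mf$pi[2])
    tau2[i] <- mf$tau2
  }
  per_cluster <- purrr::imap_dfr(preds, function(d, cl) {
    tibble::tibble(cluster = cl, grid = d$grid, estimate = d$estimate)
  })
  new_calibration_curve(
    tibble::tibble(grid = grid, estimate = est, ci_lo = ci_lo, ci_hi = ci_hi,
                   pi_lo = pi_lo, pi_hi = pi_hi, tau2 = tau2),
    method_tag = paste0("2mac_", smoother), level = level,
    per_cluster = per_cluster,
    extra = list(smoother = smoother, cluster_fits = fits))
}

#' Flexible calibration curve ignoring clustering
#'
#' The conventional single-model calibration curve: a pooled logistic
#' regression of the outcome on a restricted cubic spline (3 knots) of the
#' logit predicted risk, fitted to all rows as if they were independent.
#' Serves as the cluster-ignorant baseline; no prediction interval exists
#' because no between-cluster model is fitted.
#'
#' @inheritParams cal_2mac
#' @param k Number of spline knots.
#' @return A `calibration_curve` with `method_tag = "ignore"` and missing
#'   PI columns.
#' @export
cal_ignore <- function(data, grid_size = 100, level = 0.95, k = 3) {
  data <- ensure_cp(data)
  x <- logit(data$p)
  kn <- place_knots(x, k)
  fit <- fit_logistic(data$y, cbind(1, rcs_basis(x, kn)),
                      kind = "logistic_rcs", knots = kn)
  grid <- seq(0.01, 0.99, length.out = grid_size)
  pr <- predict_observed_proportion(fit, grid)
  zc <- stats::qnorm(1 - (1 - level) / 2)
  eta <- logit(clip_prob(pr$estimate))
  new_calibration_curve(
    tibble::tibble(grid = grid, estimate = pr$estimate,
                   ci_lo = expit(eta - zc * pr$se_logit),
                   ci_hi = expit(eta + zc * pr$se_logit),
                   pi_lo = NA_real_, pi_hi = NA_real_),
    method_tag = "ignore", level = level, extra = list(fit = fit))
}
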