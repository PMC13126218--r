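#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy a univariate meta-analysis fit
#'
#' @param x A `meta_fit` from [meta_uni()].
#' @param ... Unused.
#' @return A one-row tibble with the pooled estimate, its standard error
#'   and the CI/PI bounds.
#' @exportS3Method generics::tidy
tidy.meta_fit <- function(x, ...) {
  tibble::tibble(term = "mu", estimate = x$mu, std.error = x$se_mu,
                 conf.low = x$ci[1], conf.high = x$ci[2],
                 pi.low = x$pi[1], pi.high = x$pi[2])
}

#' @rdname tidy.meta_fit
#' @exportS3Method generics::glance
glance.meta_fit <- function(x, ...) {
  tibble::tibble(tau2 = x$tau2, k = x$k, method = x$method, level = x$level)
}

#' Tidy a bivariate meta-analysis fit
#'
#' @param x A `biv_meta_fit` from [meta_biv()].
#' @param ... Unused.
#' @exportS3Method generics::tidy
tidy.biv_meta_fit <- function(x, ...) {
  tibble::tibble(term = c("mu_x", "mu_y"), estimate = x$mu,
                 std.error = sqrt(diag(x$cov_mu)),
                 conf.low = x$ci[, "lo"], conf.high = x$ci[, "hi"],
                 pi.low = x$pi[, "lo"], pi.high = x$pi[, "hi"])
}

#' @rdname tidy.biv_meta_fit
#' @exportS3Method generics::glance
glance.biv_meta_fit <- function(x, ...) {
  tibble::tibble(tau2_x = x$Sigma_B[1, 1], tau2_y = x$Sigma_B[2, 2],
                 rho_B = stats::cov2cor(x$Sigma_B + diag(1e-12, 2))[1, 2],
                 k = x$k, fallback = x$fallback, level = x$level)
}

#' Tidy a mixed-model calibration fit
#'
#' @param x A `mixc_fit` from [fit_mixc()].
#' @param ... Unused.
#' @return Fixed-effect estimates with standard errors.
#' @exportS3Method generics::tidy
tidy.mixc_fit <- function(x, ...) {
  tibble::tibble(term = names(x$fixed), estimate = unname(x$fixed),
                 std.error = sqrt(diag(x$fixed_cov)))
}

#' @rdname tidy.mixc_fit
#' @exportS3Method generics::glance
glance.mixc_fit <- function(x, ...) {
  tibble::tibble(logLik = x$loglik_laplace,
                 sigma_u_frobenius = norm(x$Sigma_u, "F"),
                 n_clusters = nrow(x$eb),
                 converged = x$converged,
                 diagonal_fallback = x$diagonal_fallback)
}

#' Tidy / summarise a calibration curve
#'
#' `tidy()` returns the per-grid-point tibble; `glance()` a one-row
#' summary (method, level, number of points, mean CI and PI widths).
#'
#' @param x A `calibration_curve`.
#' @param ... Unused.
#' @exportS3Method generics::tidy
tidy.calibration_curve <- function(x, ...) {
  tibble::as_tibble(x)
}

#' @rdname tidy.calibration_curve
#' @exportS3Method generics::glance
glance.calibration_curve <- function(x, ...) {
  tibble::tibble(method = attr(x, "method_tag"), level = attr(x, "level"),
                 n_points = nrow(x),
                 mean_ci_width = mean(x$ci_hi - x$ci_lo, na.rm = TRUE),
                 mean_pi_width = if (all(!is.finite(x$pi_lo)))
                   NA_real_ else mean(x$pi_hi - x$pi_lo, na.rm = TRUE))
}
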