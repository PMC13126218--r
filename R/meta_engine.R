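#' Univariate random-effects meta-analysis with known within-cluster variance
#'
#' Pools k cluster-level estimates with known sampling variances under the
#' standard random-effects model. The between-cluster variance tau^2 is
#' estimated by REML (default) with a DerSimonian-Laird fallback on
#' non-convergence. The confidence interval is z-based; the prediction
#' interval for the estimate in a new cluster uses the t-based
#' Higgins-Thompson-Spiegelhalter form with k - 2 degrees of freedom,
#' `mu +/- t_{0.975, k-2} sqrt(tau2 + se_mu^2)`, and is reported as missing
#' for k < 3.
#'
#' @param theta Numeric vector of cluster estimates (length k >= 2).
#' @param v Within-cluster sampling variances (> 0), same length.
#' @param method `"REML"` (default) or `"DL"`.
#' @param level Coverage level of CI and PI.
#' @return A `meta_fit` list with elements `mu`, `se_mu`, `tau2`, `k`,
#'   `method`, `ci`, `pi` and `level`.
#' @export
#' @examples
#' meta_uni(c(0.1, 0.3, 0.2), c(0.01, 0.02, 0.015))
meta_uni <- function(theta, v, method = c("REML", "DL"), level = 0.95) {
  method <- match.arg(method)
  k <- length(theta)
  if (k < 2) stop("need at least 2 clusters to pool", call. = FALSE)
  if (length(v) != k || any(!is.finite(theta)) || any(!is.finite(v)) ||
      any(v <= 0)) {
    stop("`theta` and `v` must be finite with v > 0", call. = FALSE)
  }
  used <- method
  res <- tryCatch(
    suppressWarnings(metafor::rma.uni(yi = theta, vi = v, method = method,
                                      test = "z")),
    error = function(e) NULL)
  if (is.null(res)) {
    used <- "DL"
    res <- suppressWarnings(metafor::rma.uni(yi = theta, vi = v,
                                             method = "DL", test = "z"))
  }
  mu <- as.numeric(res$beta)
  se <- res$se
  tau2 <- max(res$tau2, 0)
  alpha <- 1 - level
  zc <- stats::qnorm(1 - alpha / 2)
  ci <- c(mu - zc * se, mu + zc * se)
  pi <- if (k >= 3) {
    tc <- stats::qt(1 - alpha / 2, df = k - 2)
    hw <- tc * sqrt(tau2 + se^2)
    c(mu - hw, mu + hw)
  } else {
    c(NA_real_, NA_real_)
  }
  structure(list(mu = mu, se_mu = se, tau2 = tau2, k = k, method = used,
                 ci = ci, pi = pi, level = level),
            class = "meta_fit")
}

#' @export
print.meta_fit <- function(x, ...) {
  cat("<meta_fit> mu=", signif(x$mu, 5), " (se ", signif(x$se_mu, 4),
      "), tau2=", signif(x$tau2, 4), ", k=", x$k, ", ", x$method, "\n",
      sep = "")
  invisible(x)
}

#' Bivariate random-effects meta-analysis
#'
#' Jointly pools paired cluster-level estimates (here: mean logit predicted
#' risk and logit observed proportion within a risk group) with known
#' within-cluster covariance matrices, allowing an unstructured 2 x 2
#' between-cluster covariance. Fitting is by REML via
#' [metafor::rma.mv()]; if the bivariate optimiser fails the function falls
#' back to two independent univariate pools (between-cluster correlation 0)
#' with a warning. Per-coordinate CI and PI follow the same conventions as
#' [meta_uni()].
#'
#' @param theta k x 2 matrix of cluster estimates.
#' @param V List of k positive semi-definite 2 x 2 within-cluster covariance
#'   matrices.
#' @param level Coverage level.
#' @return A `biv_meta_fit` list: `mu` (length 2), `cov_mu` (2 x 2),
#'   `Sigma_B` (2 x 2 between-cluster covariance), `k`, `ci` and `pi`
#'   (2 x 2 matrices, one row per coordinate), `fallback` flag.
#' @export
meta_biv <- function(theta, V, level = 0.95) {
  theta <- as.matrix(theta)
  k <- nrow(theta)
  if (k < 2) stop("need at least 2 clusters to pool", call. = FALSE)
  stopifnot(ncol(theta) == 2, length(V) == k)
  yi <- as.vector(t(theta))
  outcome <- factor(rep(c("x", "y"), k), levels = c("x", "y"))
  cluster <- rep(seq_len(k), each = 2)
  Vmat <- matrix(0, 2 * k, 2 * k)
  for (j in seq_len(k)) {
    idx <- (2 * j - 1):(2 * j)
    Vmat[idx, idx] <- V[[j]]
  }
  res <- tryCatch(
    suppressWarnings(metafor::rma.mv(
      yi, V = Vmat, mods = ~ outcome - 1,
      random = ~ outcome | cluster, struct = "UN",
      control = list(iter.max = 500, rel.tol = 1e-9))),
    error = function(e) NULL)
  alpha <- 1 - level
  zc <- stats::qnorm(1 - alpha / 2)
  tc <- if (k >= 3) stats::qt(1 - alpha / 2, df = k - 2) else NA_real_
  if (!is.null(res)) {
    mu <- as.numeric(res$beta)
    cov_mu <- as.matrix(res$vb)
    tau2 <- pmax(res$tau2, 0)
    rho <- if (length(res$rho) == 1) res$rho else 0
    Sigma_B <- matrix(c(tau2[1], rho * sqrt(prod(tau2)),
                        rho * sqrt(prod(tau2)), tau2[2]), 2, 2)
    fallback <- FALSE
  } else {
    warning("bivariate REML failed; falling back to independent univariate ",
            "pools", call. = FALSE)
    f1 <- meta_uni(theta[, 1], vapply(V, function(m) m[1, 1], numeric(1)),
                   level = level)
    f2 <- meta_uni(theta[, 2], vapply(V, function(m) m[2, 2], numeric(1)),
                   level = level)
    mu <- c(f1$mu, f2$mu)
    cov_mu <- diag(c(f1$se_mu^2, f2$se_mu^2))
    Sigma_B <- diag(c(f1$tau2, f2$tau2))
    fallback <- TRUE
  }
  se <- sqrt(diag(cov_mu))
  ci <- cbind(mu - zc * se, mu + zc * se)
  pi <- if (k >= 3) {
    hw <- tc * sqrt(diag(Sigma_B) + se^2)
    cbind(mu - hw, mu + hw)
  } else {
    matrix(NA_real_, 2, 2)
  }
  dimnames(ci) <- dimnames(pi) <- list(c("x", "y"), c("lo", "hi"))
  structure(list(mu = mu, cov_mu = cov_mu, Sigma_B = Sigma_B, k = k,
                 ci = ci, pi = pi, level = level, fallback = fallback),
            class = "biv_meta_fit")
}

#' @export
print.biv_meta_fit <- function(x, ...) {
  cat("<biv_meta_fit> mu=(", paste(signif(x$mu, 5), collapse = ", "),
      "), k=", x$k, if (x$fallback) " [univariate fallback]" else "",
      "\n", sep = "")
  invisible(x)
}
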