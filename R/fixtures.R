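#' Generate small deterministic clustered-prediction datasets
#'
#' Quick fixtures for tests, examples and documentation. Predicted risks
#' are drawn logit-normally around an event rate of 30%; outcomes are then
#' generated under one of three truths:
#' \describe{
#'   \item{`calibrated`}{`y ~ Bernoulli(p)`: the predictions are perfect.}
#'   \item{`miscalibrated`}{true logit risk `= -0.5 + 1.5 logit(p)`,
#'     a fixed intercept/slope distortion shared by all clusters.}
#'   \item{`heterogeneous`}{cluster-specific distortion: intercepts drawn
#'     with variance 0.8225 (the random-intercept variance of a 20% ICC
#'     logistic model) and slopes `1 + N(0, 0.2^2)`.}
#' }
#'
#' @param kind One of `"calibrated"`, `"miscalibrated"`,
#'   `"heterogeneous"`.
#' @param n_clusters,n_per Number of clusters and rows per cluster.
#' @param seed Integer seed; the same seed reproduces the data exactly.
#' @return A `clustered_predictions` tibble.
#' @export
#' @examples
#' make_fixture("calibrated", n_clusters = 5, n_per = 50, seed = 1)
make_fixture <- function(kind = c("calibrated", "miscalibrated",
                                  "heterogeneous"),
                         n_clusters = 10, n_per = 500, seed = 1) {
  kind <- match.arg(kind)
  gen <- function() {
    cl <- rep(sprintf("C%02d", seq_len(n_clusters)), each = n_per)
    p <- expit(stats::rnorm(n_clusters * n_per, mean = logit(0.3), sd = 1))
    eta <- switch(kind,
      calibrated = logit(p),
      miscalibrated = -0.5 + 1.5 * logit(p),
      heterogeneous = {
        a <- stats::rnorm(n_clusters, sd = sqrt(0.8225))
        b <- 1 + stats::rnorm(n_clusters, sd = 0.2)
        idx <- rep(seq_len(n_clusters), each = n_per)
        a[idx] + b[idx] * logit(p)
      })
    y <- as.integer(stats::runif(n_clusters * n_per) < expit(eta))
    tibble::tibble(cluster = cl, y = y, p = p)
  }
  as_clustered_predictions(withr::with_seed(seed, gen()))
}
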