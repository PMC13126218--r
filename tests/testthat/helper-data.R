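# Shared fixtures built in code at test time.

tiny_csv <- function(df) {
  path <- tempfile(fileext = ".csv")
  readr::write_csv(df, path, progress = FALSE)
  path
}

# A many-cluster table with known labels for the merge tests.
labelled_cp <- function(n_labels, n_per = 5, seed = 11) {
  withr::with_seed(seed, {
    cl <- rep(sprintf("L%02d", seq_len(n_labels)), each = n_per)
    tibble::tibble(cluster = cl,
                   y = stats::rbinom(length(cl), 1, 0.4),
                   p = stats::runif(length(cl), 0.05, 0.95))
  })
}

# Perfectly calibrated clustered sample: y ~ Bernoulli(p), common risk
# distribution across clusters.
calibrated_cp <- function(n_clusters, n_per, seed) {
  make_fixture("calibrated", n_clusters = n_clusters, n_per = n_per,
               seed = seed)
}
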