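#' Assign per-cluster risk groups
#'
#' `assign_groups_quantile()` splits each cluster into `Q` groups of
#' near-equal size by sorted predicted risk (the clustered analogue of
#' decile grouping; ties broken by stable row order). Group sizes within a
#' cluster differ by at most 1. `assign_groups_interval()` instead cuts the
#' probability space (0, 1) into `Q` equally spaced right-closed intervals,
#' so clusters need not appear in every group.
#'
#' @param data A `clustered_predictions` tibble (or coercible).
#' @param Q Number of groups (>= 2).
#' @return An integer vector of group indices (1..Q), one per row of `data`.
#' @export
assign_groups_quantile <- function(data, Q = 10) {
  data <- ensure_cp(data)
  stopifnot(Q >= 2)
  sizes <- table(data$cluster)
  small <- names(sizes)[sizes < Q]
  if (length(small) > 0) {
    stop("cluster(s) with fewer than Q = ", Q, " rows: ",
         paste(small, collapse = ", "),
         "; consider merge_clusters() first", call. = FALSE)
  }
  g <- integer(nrow(data))
  for (cl in unique(data$cluster)) {
    idx <- which(data$cluster == cl)
    n <- length(idx)
    sz <- rep(n %/% Q, Q)
    if (n %% Q > 0) sz[seq_len(n %% Q)] <- sz[seq_len(n %% Q)] + 1L
    ord <- idx[order(data$p[idx])]  # radix order is stable in ties
    g[ord] <- rep(seq_len(Q), sz)
  }
  g
}

#' @rdname assign_groups_quantile
#' @export
assign_groups_interval <- function(data, Q = 10) {
  data <- ensure_cp(data)
  stopifnot(Q >= 2)
  # interval g is ((g-1)/Q, g/Q], first interval closed at 0
  g <- ceiling(data$p * Q)
  g[g < 1L] <- 1L
  g[g > Q] <- Q
  as.integer(g)
}

#' Summarise one cluster-group for bivariate pooling
#'
#' Computes, for the rows of a single cluster within a single risk group,
#' the logit observed proportion and the mean logit predicted risk together
#' with their sampling variances. Boundary event counts (0 or n) receive a
#' 0.5 continuity correction so logits stay finite; singleton groups get a
#' large sentinel variance (1e6) for the mean logit risk, giving them
#' effectively zero weight.
#'
#' @param y Binary outcomes of the rows in the cluster-group.
#' @param p Predicted risks of those rows.
#' @return A one-row tibble: `n`, `events`, `mean_logit_p`,
#'   `var_mean_logit_p`, `logit_prev`, `var_logit_prev`.
#' @export
summarize_group <- function(y, p) {
  n <- length(y)
  stopifnot(n >= 1, length(p) == n)
  events <- sum(y)
  boundary <- events == 0 || events == n
  cc <- if (boundary) 0.5 else 0
  logit_prev <- logit((events + cc) / (n + 2 * cc))
  var_logit_prev <- 1 / (events + cc) + 1 / (n - events + cc)
  lp <- logit(p)
  mean_logit_p <- mean(lp)
  var_mean_logit_p <- if (n == 1) 1e6 else max(stats::var(lp) / n, 1e-8)
  tibble::tibble(n = n, events = events, mean_logit_p = mean_logit_p,
                 var_mean_logit_p = var_mean_logit_p,
                 logit_prev = logit_prev, var_logit_prev = var_logit_prev)
}

#' Clustered group calibration (CG-C)
#'
#' Grouped calibration for clustered data: within every cluster the
#' predictions are split into `Q` groups (per-cluster quantiles, or fixed
#' intervals of the probability space), each cluster-group is summarised by
#' its mean logit predicted risk and logit observed proportion, and the
#' summaries of each group are pooled across clusters with a bivariate
#' random-effects meta-analysis. The resulting `Q` pooled points (with CI
#' and PI from the between-cluster heterogeneity) form the calibration
#' curve. Groups reaching fewer than 2 clusters are dropped with a warning.
#'
#' @inheritParams assign_groups_quantile
#' @param grouping `"quantile"` (default) or `"interval"`.
#' @param level Coverage level for CI and PI.
#' @param rho_w Within-cluster correlation between the two summaries
#'   supplied to the bivariate pooling step (default 0).
#' @return A `calibration_curve` with up to `Q` points; `method_tag` is
#'   `"cgc_quantile"` or `"cgc_interval"`. The per-group pooled fits are
#'   kept in the `extra` attribute.
#' @export
#' @examples
#' d <- make_fixture("calibrated", n_clusters = 6, n_per = 120, seed = 1)
#' cal_cgc(d, Q = 5)
cal_cgc <- function(data, Q = 10, grouping = c("quantile", "interval"),
                    level = 0.95, rho_w = 0) {
  data <- ensure_cp(data)
  grouping <- match.arg(grouping)
  g <- switch(grouping,
              quantile = assign_groups_quantile(data, Q),
              interval = assign_groups_interval(data, Q))
  data$group <- g
  summ <- data |>
    dplyr::group_by(.data$group, .data$cluster) |>
    dplyr::summarise(summarize_group(.data$y, .data$p), .groups = "drop")
  fits <- list()
  rows <- list()
  for (q in sort(unique(summ$group))) {
    sq <- summ[summ$group == q, ]
    if (nrow(sq) < 2) {
      warning("group ", q, " has fewer than 2 contributing clusters; dropped",
              call. = FALSE)
      next
    }
    V <- lapply(seq_len(nrow(sq)), function(i) {
      s1 <- sqrt(sq$var_mean_logit_p[i])
      s2 <- sqrt(sq$var_logit_prev[i])
      matrix(c(s1^2, rho_w * s1 * s2, rho_w * s1 * s2, s2^2), 2, 2)
    })
    bf <- meta_biv(cbind(sq$mean_logit_p, sq$logit_prev), V, level = level)
    fits[[as.character(q)]] <- bf
    rows[[as.character(q)]] <- tibble::tibble(
      group = q,
      grid = expit(bf$mu[1]),
      estimate = expit(bf$mu[2]),
      ci_lo = expit(bf$ci["y", "lo"]), ci_hi = expit(bf$ci["y", "hi"]),
      pi_lo = expit(bf$pi["y", "lo"]), pi_hi = expit(bf$pi["y", "hi"]),
      k_clusters = bf$k)
  }
  if (length(rows) == 0) {
    stop("all groups were dropped; cannot build a CG-C curve", call. = FALSE)
  }
  df <- dplyr::bind_rows(rows)
  df <- df[order(df$grid), ]
  if (anyDuplicated(df$grid)) {
    df <- df[!duplicated(df$grid), ]
  }
  new_calibration_curve(df[, c("grid", "estimate", "ci_lo", "ci_hi",
                               "pi_lo", "pi_hi", "group", "k_clusters")],
                        method_tag = paste0("cgc_", grouping), level = level,
                        extra = list(group_fits = fits, Q = Q))
}
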