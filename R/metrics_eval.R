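#' Mean squared calibration error
#'
#' Mean squared difference, on the probability scale, between the estimated
#' observed proportions of a calibration curve and the true observed
#' proportions on the same grid. Points where either side is missing are
#' excluded pairwise. For grouped (CG-C) curves the comparison runs over
#' the curve's own points.
#'
#' @param curve A `calibration_curve`, or a numeric vector of estimates.
#' @param truth Numeric vector of true observed proportions on the same
#'   grid.
#' @return A single non-negative number.
#' @export
msce <- function(curve, truth) {
  est <- if (inherits(curve, "calibration_curve")) curve$estimate else curve
  if (length(est) != length(truth)) {
    stop("`curve` and `truth` must share a grid", call. = FALSE)
  }
  ok <- is.finite(est) & is.finite(truth)
  if (!any(ok)) stop("no overlapping points to compare", call. = FALSE)
  mean((est[ok] - truth[ok])^2)
}

#' Pointwise prediction-interval coverage
#'
#' For each grid point, the proportion of clusters whose true
#' cluster-specific observed proportion falls inside the curve's prediction
#' interval. Points with an undefined PI are reported as `NA`.
#'
#' @param curve A `calibration_curve` with `pi_lo`/`pi_hi` columns.
#' @param cluster_truths Matrix of true values, one row per cluster, one
#'   column per grid point.
#' @return Numeric vector of coverage proportions over the grid.
#' @export
pi_coverage <- function(curve, cluster_truths) {
  stopifnot(inherits(curve, "calibration_curve"))
  cluster_truths <- as.matrix(cluster_truths)
  if (ncol(cluster_truths) != nrow(curve)) {
    stop("`cluster_truths` must have one column per grid point",
         call. = FALSE)
  }
  vapply(seq_len(nrow(curve)), function(i) {
    lo <- curve$pi_lo[i]
    hi <- curve$pi_hi[i]
    if (!is.finite(lo) || !is.finite(hi)) return(NA_real_)
    tr <- cluster_truths[, i]
    mean(tr >= lo & tr <= hi, na.rm = TRUE)
  }, numeric(1))
}

fit_method_curve <- function(cp, method, grid_size, seed, mixc_nAGQ = 1) {
  switch(method,
    ignore = cal_ignore(cp, grid_size = grid_size),
    cgc_quantile = cal_cgc(cp, Q = 10, grouping = "quantile"),
    cgc_interval = cal_cgc(cp, Q = 10, grouping = "interval"),
    `2mac_rcs` = cal_2mac(cp, smoother = "rcs", grid_size = grid_size),
    `2mac_loess` = cal_2mac(cp, smoother = "loess", grid_size = grid_size),
    mixc = cal_mixc(cp, grid_size = grid_size, n_draws = 2000, seed = seed,
                    nAGQ = mixc_nAGQ),
    stop("unknown method: ", method, call. = FALSE))
}

#' Run a clustered-calibration simulation experiment
#'
#' Repeatedly draws validation (or development) samples from a
#' superpopulation, applies the requested calibration methods, and scores
#' each estimated curve against the truth of the data-generating model:
#' mean squared calibration error against the average-cluster truth
#' (random intercept set to 0) and pointwise PI coverage against the
#' cluster-specific truths of all superpopulation clusters.
#'
#' In `"vary_validation"` mode one prediction model is trained up front
#' from a single cluster with near-average event rate (training size
#' `dev_n`), and each replicate draws a fresh validation sample of
#' `n_clusters` clusters at `epc` events per cluster. In
#' `"vary_development"` mode each replicate trains a fresh model on a drawn
#' development sample and validates it on a large held-out sample
#' (`val_clusters` clusters, `val_n` rows).
#'
#' @param sp A `superpopulation`.
#' @param epc,n_clusters Scenario factors (events per cluster; number of
#'   clusters in the varied sample).
#' @param methods Character vector among `"ignore"`, `"cgc_quantile"`,
#'   `"cgc_interval"`, `"2mac_rcs"`, `"2mac_loess"`, `"mixc"`.
#' @param n_reps Number of replicates.
#' @param master_seed Integer; per-replicate seeds are derived from it.
#' @param mode `"vary_validation"` or `"vary_development"`.
#' @param grid_size Evaluation grid size (default 100 points, 0.01-0.99).
#' @param dev_n Training size in `"vary_validation"` mode.
#' @param val_clusters,val_n Held-out validation dimensions in
#'   `"vary_development"` mode.
#' @param coverage Compute PI coverage (slightly slower); default `TRUE`.
#' @param mixc_nAGQ Integration accuracy for MIX-C fits inside the
#'   experiment loop; defaults to the fast `nAGQ = 0` approximation, which
#'   tracks the Laplace fit closely at a fraction of the cost.
#' @return An `experiment_result` tibble with one row per replicate and
#'   method: `replicate`, `method`, `msce`, `failed` and a `coverage`
#'   list-column of per-grid-point coverage vectors.
#' @export
run_experiment <- function(sp, epc, n_clusters,
                           methods = c("ignore", "cgc_quantile",
                                       "2mac_rcs", "mixc"),
                           n_reps = 10, master_seed = 1,
                           mode = c("vary_validation", "vary_development"),
                           grid_size = 100, dev_n = 1711,
                           val_clusters = 30, val_n = 100000,
                           coverage = TRUE, mixc_nAGQ = 0) {
  stopifnot(inherits(sp, "superpopulation"))
  mode <- match.arg(mode)
  grid <- seq(0.01, 0.99, length.out = grid_size)
  seeds <- withr::with_seed(master_seed,
                            sample.int(.Machine$integer.max - 1, n_reps + 1))
  spec <- sp$spec

  predictor <- NULL
  truth0 <- NULL
  truths_cl <- NULL
  dev_cluster <- character(0)
  if (mode == "vary_validation") {
    prevs <- tapply(sp$data$y, sp$data$cluster, mean)
    dev_cluster <- names(which.min(abs(prevs - mean(sp$data$y))))
    rows <- sp$data[sp$data$cluster == dev_cluster, ]
    train <- withr::with_seed(seeds[n_reps + 1],
                              rows[sample(nrow(rows),
                                          min(dev_n, nrow(rows))), ])
    predictor <- train_prediction_model(train)
    xs <- true_curve_x(predictor, grid, sp = sp)
    truth0 <- if (xs$monotone) expit(true_logit(spec, xs$x, 0)) else
      xs$empirical
    if (coverage) {
      truths_cl <- t(vapply(sp$u, function(uj) {
        if (xs$monotone) expit(true_logit(spec, xs$x, uj)) else xs$empirical
      }, numeric(grid_size)))
    }
  }

  out <- vector("list", n_reps * length(methods))
  idx <- 1
  for (r in seq_len(n_reps)) {
    rs <- seeds[r]
    if (mode == "vary_validation") {
      val <- draw_scenario(sp, n_clusters, epc, seed = rs,
                           exclude = dev_cluster)
      pred_r <- predictor
      truth0_r <- truth0
      truths_r <- truths_cl
    } else {
      dev <- draw_scenario(sp, n_clusters, epc, seed = rs)
      pred_r <- train_prediction_model(dev)
      val <- draw_validation(sp, n_clusters = val_clusters, n_total = val_n,
                             seed = rs + 1,
                             exclude = unique(dev$cluster))
      xs <- true_curve_x(pred_r, grid, sp = sp)
      truth0_r <- if (xs$monotone) expit(true_logit(spec, xs$x, 0)) else
        xs$empirical
      truths_r <- if (coverage) {
        t(vapply(sp$u, function(uj) {
          if (xs$monotone) expit(true_logit(spec, xs$x, uj)) else
            xs$empirical
        }, numeric(grid_size)))
      } else NULL
    }
    cp <- apply_predictor(val, pred_r)
    for (m in methods) {
      curve <- tryCatch(
        suppressWarnings(fit_method_curve(cp, m, grid_size, seed = rs,
                                          mixc_nAGQ = mixc_nAGQ)),
        error = function(e) NULL)
      if (is.null(curve)) {
        out[[idx]] <- tibble::tibble(replicate = r, method = m,
                                     msce = NA_real_, failed = TRUE,
                                     coverage = list(NULL))
        idx <- idx + 1
        next
      }
      if (startsWith(m, "cgc")) {
        # grouped curves are scored at their own points
        xs_m <- true_curve_x(pred_r, curve$grid, sp = sp)
        tr_m <- if (xs_m$monotone) expit(true_logit(spec, xs_m$x, 0)) else
          xs_m$empirical
        ms <- msce(curve, tr_m)
        cov_v <- if (coverage) {
          tcl <- t(vapply(sp$u, function(uj) {
            if (xs_m$monotone) expit(true_logit(spec, xs_m$x, uj)) else
              xs_m$empirical
          }, numeric(nrow(curve))))
          pi_coverage(curve, tcl)
        } else NULL
      } else {
        ms <- msce(curve, truth0_r)
        cov_v <- if (coverage && !all(is.na(curve$pi_lo))) {
          pi_coverage(curve, truths_r)
        } else NULL
      }
      out[[idx]] <- tibble::tibble(replicate = r, method = m, msce = ms,
                                   failed = FALSE, coverage = list(cov_v))
      idx <- idx + 1
    }
  }
  res <- dplyr::bind_rows(out)
  attr(res, "scenario") <- list(icc = spec$icc_target, auc = spec$auc_target,
                                epc = epc, n_clusters = n_clusters,
                                mode = mode, n_reps = n_reps,
                                grid_size = grid_size)
  class(res) <- c("experiment_result", class(res))
  res
}

#' Summarise an experiment result
#'
#' Aggregates per-replicate MSCE to the median and interquartile range,
#' reported multiplied by 100 (the conventional table scale), plus mean PI
#' coverage over a central grid region.
#'
#' @param result An `experiment_result` from [run_experiment()].
#' @param central Probability range over which coverage is averaged.
#' @return A tibble with one row per method.
#' @export
summarize_experiment <- function(result, central = c(0.1, 0.6)) {
  sc <- attr(result, "scenario")
  grid <- seq(0.01, 0.99, length.out = sc$grid_size)
  in_central <- grid >= central[1] & grid <= central[2]
  result |>
    dplyr::group_by(.data$method) |>
    dplyr::summarise(
      n_ok = sum(!.data$failed),
      msce_median_x100 = stats::median(.data$msce, na.rm = TRUE) * 100,
      msce_q1_x100 = stats::quantile(.data$msce, 0.25, na.rm = TRUE) * 100,
      msce_q3_x100 = stats::quantile(.data$msce, 0.75, na.rm = TRUE) * 100,
      coverage_central = {
        covs <- .data$coverage[!.data$failed]
        vals <- unlist(lapply(covs, function(v) {
          if (is.null(v)) return(NULL)
          if (length(v) == sc$grid_size) v[in_central] else v
        }))
        if (length(vals) == 0) NA_real_ else mean(vals, na.rm = TRUE)
      },
      .groups = "drop")
}
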