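#' Validate a table of clustered risk predictions
#'
#' Standardises a data frame of per-individual risk predictions into the
#' canonical long format used throughout the package: one row per individual
#' with a cluster label, a binary outcome and a predicted risk. Predicted
#' risks of exactly 0 or 1 are clipped into the open unit interval so that
#' logit transforms stay finite.
#'
#' @param data A data frame with one row per individual.
#' @param cluster,y,p Column names (strings) holding the cluster label, the
#'   binary outcome (0/1) and the predicted risk in (0,1).
#' @param clip Half-width of the clipping boundary; predicted risks are
#'   clipped to `[clip, 1 - clip]` with a warning. Default `1e-5`.
#'
#' @return A tibble of class `clustered_predictions` with columns `cluster`
#'   (character), `y` (integer 0/1) and `p` (double in the open unit
#'   interval). Cluster levels are ordered by first appearance.
#' @export
#' @examples
#' d <- data.frame(cluster = c("A", "A", "B"), y = c(0, 1, 1),
#'                 p = c(0.2, 0.8, 0.5))
#' as_clustered_predictions(d)
as_clustered_predictions <- function(data, cluster = "cluster", y = "y",
                                     p = "p", clip = 1e-5) {
  stopifnot(is.data.frame(data))
  for (col in c(cluster, y, p)) {
    if (!col %in% names(data)) {
      stop("column `", col, "` not found in `data`", call. = FALSE)
    }
  }
  out <- tibble::tibble(
    cluster = as.character(data[[cluster]]),
    y = data[[y]],
    p = as.numeric(data[[p]])
  )
  if (any(is.na(out$cluster)) || any(out$cluster == "")) {
    stop("missing cluster labels in rows ",
         paste(utils::head(which(is.na(out$cluster) | out$cluster == ""), 5),
               collapse = ", "), call. = FALSE)
  }
  bad_y <- which(!(out$y %in% c(0, 1)))
  if (length(bad_y) > 0) {
    stop("outcome `", y, "` must be 0 or 1; offending row(s): ",
         paste(utils::head(bad_y, 5), collapse = ", "), call. = FALSE)
  }
  out$y <- as.integer(out$y)
  bad_p <- which(!is.finite(out$p) | out$p < 0 | out$p > 1)
  if (length(bad_p) > 0) {
    stop("predicted risk `", p, "` must lie in [0, 1]; offending row(s): ",
         paste(utils::head(bad_p, 5), collapse = ", "), call. = FALSE)
  }
  n_clip <- sum(out$p < clip | out$p > 1 - clip)
  if (n_clip > 0) {
    warning(n_clip, " predicted risk(s) clipped to [", clip, ", 1 - ", clip,
            "]", call. = FALSE)
    out$p <- pmin(pmax(out$p, clip), 1 - clip)
  }
  new_clustered_predictions(out)
}

new_clustered_predictions <- function(x) {
  class(x) <- c("clustered_predictions", class(tibble::tibble()))
  x
}

#' @export
print.clustered_predictions <- function(x, ...) {
  cat("<clustered_predictions> ", nrow(x), " individuals in ",
      dplyr::n_distinct(x$cluster), " clusters; event rate ",
      sprintf("%.3f", mean(x$y)), "\n", sep = "")
  NextMethod()
}

#' Read clustered predictions from a CSV file
#'
#' @param path Path to a comma-separated file with a header row.
#' @param cluster_col,y_col,p_col Names of the columns holding the cluster
#'   label, outcome and predicted risk.
#' @inheritParams as_clustered_predictions
#' @return A validated [as_clustered_predictions()] tibble.
#' @export
read_predictions <- function(path, cluster_col = "cluster", y_col = "y",
                             p_col = "p", clip = 1e-5) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  raw <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  as_clustered_predictions(raw, cluster = cluster_col, y = y_col, p = p_col,
                           clip = clip)
}

#' Merge clusters by relabelling
#'
#' Pools clusters by mapping old labels to new ones, the usual practice when
#' single centers are too small to analyse on their own. The multiset of
#' (outcome, predicted risk) pairs is unchanged; only labels move.
#'
#' @param data A `clustered_predictions` tibble (or coercible data frame).
#' @param mapping A named character vector `c(old = "new", ...)`. Labels not
#'   named are kept as is.
#' @return A relabelled `clustered_predictions` tibble.
#' @export
merge_clusters <- function(data, mapping) {
  data <- ensure_cp(data)
  stopifnot(is.character(mapping), !is.null(names(mapping)))
  unknown <- setdiff(names(mapping), unique(data$cluster))
  if (length(unknown) > 0) {
    stop("mapping refers to unknown cluster label(s): ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  hit <- data$cluster %in% names(mapping)
  data$cluster[hit] <- unname(mapping[data$cluster[hit]])
  new_clustered_predictions(data)
}

ensure_cp <- function(data) {
  if (inherits(data, "clustered_predictions")) return(data)
  as_clustered_predictions(data)
}

#' Write a calibration curve to CSV
#'
#' Writes the per-grid-point curve (estimate, CI, PI) plus, when present, one
#' wide column per cluster-specific curve. Values round-trip through
#' [read_curve()] to better than 12 significant digits.
#'
#' @param curve A `calibration_curve` (see [cal_curve()] constructors).
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_curve <- function(curve, path) {
  stopifnot(inherits(curve, "calibration_curve"))
  out <- tibble::as_tibble(curve)
  pc <- attr(curve, "per_cluster")
  if (!is.null(pc) && nrow(pc) > 0) {
    wide <- tidyr::pivot_wider(pc, names_from = "cluster",
                               values_from = "estimate",
                               names_prefix = "cluster_")
    out <- dplyr::left_join(out, wide, by = "grid")
  }
  readr::write_csv(out, path, progress = FALSE)
  invisible(path)
}

#' Read a calibration curve written by [write_curve()]
#'
#' @param path CSV path.
#' @return A `calibration_curve` tibble; per-cluster columns are folded back
#'   into the `per_cluster` attribute.
#' @export
read_curve <- function(path) {
  raw <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  cc_cols <- grep("^cluster_", names(raw), value = TRUE)
  per_cluster <- NULL
  if (length(cc_cols) > 0) {
    per_cluster <- tidyr::pivot_longer(
      raw[, c("grid", cc_cols)], dplyr::all_of(cc_cols),
      names_to = "cluster", values_to = "estimate")
    per_cluster$cluster <- sub("^cluster_", "", per_cluster$cluster)
    per_cluster <- per_cluster[, c("cluster", "grid", "estimate")]
  }
  new_calibration_curve(raw[, setdiff(names(raw), cc_cols)],
                        method_tag = attr(raw, "method_tag") %||% "unknown",
                        level = 0.95, per_cluster = per_cluster)
}

#' Construct a calibration-curve object
#'
#' Internal constructor shared by all methods. A calibration curve is a
#' tibble with one row per grid point: the predicted risk (`grid`), the
#' estimated observed proportion (`estimate`), confidence bounds
#' (`ci_lo`, `ci_hi`) and prediction bounds (`pi_lo`, `pi_hi`, `NA` where a
#' prediction interval is undefined).
#'
#' @keywords internal
new_calibration_curve <- function(df, method_tag, level = 0.95,
                                  per_cluster = NULL, extra = list()) {
  need <- c("grid", "estimate", "ci_lo", "ci_hi", "pi_lo", "pi_hi")
  for (col in setdiff(need, names(df))) df[[col]] <- NA_real_
  df <- tibble::as_tibble(df[, c(need, setdiff(names(df), need))])
  if (is.unsorted(df$grid, strictly = TRUE)) {
    stop("curve grid must be strictly increasing", call. = FALSE)
  }
  structure(df,
            class = c("calibration_curve", class(tibble::tibble())),
            method_tag = method_tag, level = level,
            per_cluster = per_cluster, extra = extra)
}

#' @export
print.calibration_curve <- function(x, ...) {
  cat("<calibration_curve> method=", attr(x, "method_tag"),
      ", level=", attr(x, "level"), ", ", nrow(x), " grid points\n", sep = "")
  NextMethod()
}

`%||%` <- function(a, b) if (is.null(a)) b else a
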