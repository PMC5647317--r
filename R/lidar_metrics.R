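#' Read height-normalized lidar returns from delimited text
#'
#' Expects one return per row with columns `x`, `y` (map units), `z` (height
#' above ground, m), `intensity`, and either a logical `is_vegetation` column
#' or an integer `class` column (point classes in `vegetation_classes` are
#' treated as vegetation). Negative heights — small artifacts of height
#' normalization — are clamped to 0 with a message. An optional
#' `return_number` column feeds the canopy-density metric.
#'
#' @param path file path.
#' @param sep field separator.
#' @param vegetation_classes point classes counted as vegetation when an
#'   `is_vegetation` column is absent (default 3, 4, 5: low/medium/high
#'   vegetation).
#' @return data.frame of returns with an `is_vegetation` column.
#' @export
read_lidar_returns <- function(path, sep = ",", vegetation_classes = c(3, 4, 5)) {
  pts <- utils::read.delim(path, sep = sep, stringsAsFactors = FALSE)
  required <- c("x", "y", "z", "intensity")
  missing <- setdiff(required, names(pts))
  if (length(missing) > 0L) {
    stop("lidar return table is missing column(s): ",
         paste(missing, collapse = ", "))
  }
  if (!"is_vegetation" %in% names(pts)) {
    if (!"class" %in% names(pts)) {
      stop("lidar return table needs an is_vegetation or class column")
    }
    pts$is_vegetation <- pts$class %in% vegetation_classes
  }
  if (any(pts$z < 0)) {
    message(sum(pts$z < 0), " negative height(s) clamped to 0")
    pts$z <- pmax(pts$z, 0)
  }
  pts
}

#' Extract vegetation returns within a circular plot footprint
#'
#' @param returns lidar return data.frame (see [read_lidar_returns()]).
#' @param centroid length-2 numeric `c(x, y)` plot centroid.
#' @param radius footprint radius, m (default 15, chosen to approximate a
#'   30 m map pixel). The boundary is inclusive.
#' @return the subset of `returns` that are vegetation and within `radius` of
#'   the centroid.
#' @export
extract_footprint <- function(returns, centroid, radius = 15) {
  if (radius <= 0) stop("radius must be positive")
  d2 <- (returns$x - centroid[1L])^2 + (returns$y - centroid[2L])^2
  keep <- returns$is_vegetation & d2 <= radius^2
  returns[keep, , drop = FALSE]
}

# Nearest-rank percentile on sorted values: deterministic and independent of
# any particular LAS-processing tool's interpolation convention.
nearest_rank <- function(x_sorted, p) {
  n <- length(x_sorted)
  x_sorted[pmax(1L, ceiling(p / 100 * n))]
}

#' Canopy structure and intensity metrics for a set of returns
#'
#' Computes the predictor suite used for biomass modeling: height percentiles
#' p10-p90 (nearest-rank), bincentiles (percentage of returns between a fixed
#' height cutoff and the maximum height), canopy cover (% of returns above
#' `cover_cutoff`), canopy density (the same proportion among first returns
#' only), mean, maximum and quadratic mean height (`sqrt(mean(z^2))`), and
#' mean + percentile intensity statistics.
#'
#' @param returns lidar return data.frame; typically the output of
#'   [extract_footprint()] or the returns of one 30 m pixel.
#' @param cover_cutoff canopy height cutoff, m (default 2).
#' @param bincentile_cutoffs height cutoffs, m, for the bincentile metrics.
#' @return one-row data.frame of named metrics plus `n_returns`; an empty
#'   return set yields all-zero metrics with `n_returns = 0`.
#' @export
compute_metrics <- function(returns, cover_cutoff = 2,
                            bincentile_cutoffs = c(2, 5, 10, 20, 30, 40, 50)) {
  pcts <- seq(10, 90, by = 10)
  metric_names <- c(
    "zmax", "zmean", "zq", paste0("p", pcts),
    paste0("b", bincentile_cutoffs), "cover", "density",
    "imean", paste0("ip", pcts)
  )
  one_row <- function(vals, n) {
    out <- as.data.frame(matrix(vals, nrow = 1L))
    names(out) <- metric_names
    out$n_returns <- n
    out
  }
  n <- nrow(returns)
  if (n == 0L) {
    return(one_row(rep(0, length(metric_names)), 0L))
  }
  z <- sort(returns$z)
  zmax <- z[n]
  first <- if ("return_number" %in% names(returns)) {
    returns$z[returns$return_number == 1L]
  } else {
    returns$z
  }
  vals <- c(
    zmax,
    mean(z),
    sqrt(mean(z^2)),
    nearest_rank(z, pcts),
    vapply(bincentile_cutoffs,
           function(cut) 100 * sum(returns$z > cut & returns$z <= zmax) / n,
           numeric(1L)),
    100 * mean(returns$z > cover_cutoff),
    if (length(first) > 0L) 100 * mean(first > cover_cutoff) else 0,
    mean(returns$intensity),
    nearest_rank(sort(returns$intensity), pcts)
  )
  one_row(vals, n)
}

#' Metric table for many plots
#'
#' Applies [compute_metrics()] to one return set per plot and binds the rows,
#' optionally joining plot attributes (e.g. ancillary predictors) by
#' `plot_id`.
#'
#' @param clouds named list of lidar return data.frames, names = plot ids.
#' @param plots optional plot table with a `plot_id` column to join.
#' @param ... passed to [compute_metrics()].
#' @return data.frame with `plot_id`, the metric columns, and any joined plot
#'   attributes.
#' @export
plot_metric_table <- function(clouds, plots = NULL, ...) {
  rows <- lapply(clouds, compute_metrics, ...)
  out <- do.call(rbind, rows)
  out <- cbind(data.frame(plot_id = names(clouds), stringsAsFactors = FALSE),
               out)
  rownames(out) <- NULL
  if (!is.null(plots)) {
    out <- merge(out, plots, by = "plot_id", sort = FALSE)
  }
  out
}

#' Gridded pixel metrics
#'
#' Assigns vegetation returns to square cells on half-open intervals
#' `[x0, x0 + cell)` and computes the metric suite per cell, yielding a
#' long-format pixel table usable as a map prediction population.
#'
#' @param returns lidar return data.frame.
#' @param origin length-2 `c(x0, y0)` grid origin.
#' @param cell cell size in map units (default 30).
#' @param ... passed to [compute_metrics()].
#' @return data.frame with cell lower-left coordinates `x0`, `y0` and one
#'   metric row per non-empty cell.
#' @export
grid_metrics <- function(returns, origin = c(0, 0), cell = 30, ...) {
  veg <- returns[returns$is_vegetation, , drop = FALSE]
  ix <- floor((veg$x - origin[1L]) / cell)
  iy <- floor((veg$y - origin[2L]) / cell)
  key <- paste(ix, iy, sep = "_")
  groups <- split(seq_len(nrow(veg)), key)
  rows <- lapply(groups, function(idx) compute_metrics(veg[idx, , drop = FALSE], ...))
  out <- do.call(rbind, rows)
  ij <- do.call(rbind, strsplit(names(groups), "_", fixed = TRUE))
  out <- cbind(
    data.frame(x0 = origin[1L] + as.numeric(ij[, 1L]) * cell,
               y0 = origin[2L] + as.numeric(ij[, 2L]) * cell),
    out
  )
  rownames(out) <- NULL
  out
}
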