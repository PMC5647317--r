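#' Predict a biomass density map over a pixel population
#'
#' Applies a fitted biomass model to every forest pixel of the county grid;
#' non-forest pixels receive `NA` (the explicit no-data value).
#'
#' @param fit a `biomass_rf`.
#' @param pixels data.frame with one row per pixel carrying the model's
#'   predictor columns, a `pixel_id`, and a logical forest-mask column.
#' @param forest_col name of the forest mask column.
#' @return data.frame `pixel_id`, `density` (Mg/ha; NA outside the mask).
#' @export
predict_map <- function(fit, pixels, forest_col = "forest") {
  stopifnot(inherits(fit, "biomass_rf"))
  missing <- setdiff(fit$predictors, names(pixels))
  if (length(missing) > 0L) {
    stop("pixels are missing predictor(s): ", paste(missing, collapse = ", "))
  }
  forest <- if (forest_col %in% names(pixels)) pixels[[forest_col]] else
    rep(TRUE, nrow(pixels))
  density <- rep(NA_real_, nrow(pixels))
  if (any(forest)) {
    density[forest] <- stats::predict(
      fit$forest, newdata = pixels[forest, fit$predictors, drop = FALSE])
  }
  data.frame(
    pixel_id = if ("pixel_id" %in% names(pixels)) pixels$pixel_id
               else seq_len(nrow(pixels)),
    density = density,
    stringsAsFactors = FALSE
  )
}

#' Area fraction and biomass total per density class
#'
#' Bins forest pixels into biomass-density categories. Fractions are over
#' forest pixels and sum to 1; per-class totals sum exactly to the county
#' total.
#'
#' @param density per-pixel densities, Mg/ha (NA = non-forest), or the output
#'   of [predict_map()].
#' @param edges strictly increasing class edges, Mg/ha; left-closed bins with
#'   the last bin open above.
#' @param area_ha pixel area, ha (default 0.09, a 30 m cell).
#' @return data.frame `class`, `n`, `fraction`, `total_mg`.
#' @export
class_distribution <- function(density,
                               edges = c(0, 50, 100, 200, 300, 400),
                               area_ha = PIXEL_AREA_HA) {
  if (is.data.frame(density)) density <- density$density
  if (is.unsorted(edges, strictly = TRUE)) {
    stop("class edges must be strictly increasing")
  }
  d <- density[!is.na(density)]
  breaks <- c(edges, Inf)
  labels <- c(paste0(utils::head(breaks, -2L), "-", breaks[-c(1L, length(breaks))]),
              paste0("> ", edges[length(edges)]))
  cls <- cut(d, breaks = breaks, labels = labels, include.lowest = TRUE,
             right = FALSE)
  out <- do.call(rbind, lapply(labels, function(lv) {
    sel <- cls == lv
    data.frame(class = lv, n = sum(sel),
               fraction = sum(sel) / length(d),
               total_mg = sum(d[sel]) * area_ha,
               stringsAsFactors = FALSE)
  }))
  out
}

#' Model-assisted estimate of the county mean and its standard error
#'
#' The difference-estimator form of the model-assisted regression estimator:
#' the naive map mean (mean of pixel predictions) is corrected by the mean
#' model error observed on the probability sample of field plots,
#' `ma_mean = map_mean - mean(predicted - observed)`, with standard error
#' `sqrt(sum((e_j - e_bar)^2) / (n (n - 1)))` from the sample residuals
#' `e_j = predicted_j - observed_j`.
#'
#' @param map per-pixel densities (Mg/ha, NA = non-forest) or the output of
#'   [predict_map()].
#' @param observed field-observed plot densities, Mg/ha.
#' @param predicted model-predicted densities for the same plots (use
#'   out-of-bag predictions to avoid optimism).
#' @param area_ha pixel area, ha.
#' @return an `ma_estimate`: `map_mean`, `ma_mean`, `se` (all Mg/ha),
#'   `total_mg` (map_mean x forest pixels x area), `n_sample`, `n_pixels`.
#' @export
ma_estimate <- function(map, observed, predicted, area_ha = PIXEL_AREA_HA) {
  if (is.data.frame(map)) map <- map$density
  if (length(observed) != length(predicted)) {
    stop("observed and predicted must have equal length")
  }
  n <- length(observed)
  if (n < 2L) stop("need at least 2 sample plots (variance undefined)")
  d <- map[!is.na(map)]
  e <- predicted - observed
  map_mean <- mean(d)
  structure(
    list(
      map_mean = map_mean,
      ma_mean = map_mean - mean(e),
      se = sqrt(sum((e - mean(e))^2) / (n * (n - 1))),
      total_mg = map_mean * length(d) * area_ha,
      n_sample = n,
      n_pixels = length(d),
      area_ha = area_ha
    ),
    class = "ma_estimate"
  )
}

#' @export
print.ma_estimate <- function(x, ...) {
  cat(sprintf(
    "Model-assisted county estimate: mean %.1f Mg/ha (map mean %.1f), SE %.2f\n",
    x$ma_mean, x$map_mean, x$se))
  cat(sprintf("  total %.2f million Mg over %d pixels (%.2f ha each), n = %d plots\n",
              x$total_mg / 1e6, x$n_pixels, x$area_ha, x$n_sample))
  invisible(x)
}

#' Compare county estimates between allometric families
#'
#' For every ordered family pair, reports the absolute difference in county
#' totals (million Mg), the percent difference (by default relative to the
#' second-named family), and — when means and standard errors are supplied —
#' the two-sample statistic `t = (m1 - m2) / sqrt(se1^2 + se2^2)` with
#' significance at 95% confidence declared when |t| > 1.96 (normal
#' approximation).
#'
#' @param totals named numeric vector of county totals in Mg, or a named list
#'   of [ma_estimate()] objects (totals, means and SEs are then extracted).
#' @param means,ses optional named vectors of (model-assisted) county means
#'   and their standard errors, Mg/ha.
#' @param reference `"second"` (default) or `"first"`: which family of the
#'   pair the percent difference is relative to.
#' @param crit critical value for the significance flag (default 1.96; set
#'   e.g. a t quantile for a degrees-of-freedom refinement).
#' @return data.frame with one row per ordered pair: `family_a`, `family_b`,
#'   `diff_million_mg`, `pct_diff`, and when available `t`,
#'   `significant_at_95`.
#' @export
compare_families <- function(totals, means = NULL, ses = NULL,
                             reference = c("second", "first"), crit = 1.96) {
  reference <- match.arg(reference)
  if (is.list(totals) && all(vapply(totals, inherits, logical(1L), "ma_estimate"))) {
    est <- totals
    totals <- vapply(est, function(e) e$total_mg, numeric(1L))
    means <- vapply(est, function(e) e$ma_mean, numeric(1L))
    ses <- vapply(est, function(e) e$se, numeric(1L))
  }
  fams <- names(totals)
  if (is.null(fams) || length(fams) < 2L) {
    stop("need at least 2 named family totals")
  }
  pairs <- utils::combn(fams, 2L)
  rows <- lapply(seq_len(ncol(pairs)), function(k) {
    a <- pairs[1L, k]; b <- pairs[2L, k]
    ref_total <- if (reference == "second") totals[[b]] else totals[[a]]
    row <- data.frame(
      family_a = a, family_b = b,
      diff_million_mg = (totals[[a]] - totals[[b]]) / 1e6,
      pct_diff = 100 * (totals[[a]] - totals[[b]]) / ref_total,
      stringsAsFactors = FALSE
    )
    if (!is.null(means) && !is.null(ses)) {
      row$t <- (means[[a]] - means[[b]]) / sqrt(ses[[a]]^2 + ses[[b]]^2)
      row$significant_at_95 <- abs(row$t) > crit
    }
    row
  })
  do.call(rbind, rows)
}

#' Per-plot discrepancy between two allometric families vs lidar structure
#'
#' Joins the signed per-plot difference between two families' density
#' estimates to the lidar structure metrics that might explain it (maximum
#' height, mean height, canopy cover) and to the mean-family biomass, then
#' summarizes the difference by canopy-height class.
#'
#' @param plot_density data.frame from [estimate_plot_biomass()] with
#'   `plot_id` and one column per family.
#' @param metrics data.frame with `plot_id`, `zmax`, `zmean`, `cover`.
#' @param family_a,family_b the two families; the difference is
#'   `family_a - family_b`.
#' @return list with `table` (plot_id, difference, zmax, zmean, cover,
#'   mean_biomass) and `by_height_class` (mean difference and count per
#'   height class).
#' @export
discrepancy_diagnostics <- function(plot_density, metrics,
                                    family_a = "crm", family_b = "jenkins") {
  need <- c(family_a, family_b)
  missing <- setdiff(need, names(plot_density))
  if (length(missing) > 0L) {
    stop("plot_density is missing famil(ies): ", paste(missing, collapse = ", "))
  }
  joined <- merge(plot_density[, c("plot_id", need)],
                  metrics[, c("plot_id", "zmax", "zmean", "cover")],
                  by = "plot_id", sort = FALSE)
  tab <- data.frame(
    plot_id = joined$plot_id,
    difference = joined[[family_a]] - joined[[family_b]],
    zmax = joined$zmax,
    zmean = joined$zmean,
    cover = joined$cover,
    mean_biomass = (joined[[family_a]] + joined[[family_b]]) / 2,
    stringsAsFactors = FALSE
  )
  cls <- cut(tab$zmax, breaks = c(0, 10, 25, 40, 55, Inf),
             labels = c("0-10 m", "10-25 m", "25-40 m", "40-55 m", "> 55 m"),
             include.lowest = TRUE, right = TRUE)
  present <- levels(cls)[levels(cls) %in% as.character(unique(cls))]
  by_height <- do.call(rbind, lapply(present, function(lv) {
    sel <- !is.na(cls) & cls == lv
    data.frame(height_class = lv, n = sum(sel),
               mean_difference = mean(tab$difference[sel]),
               stringsAsFactors = FALSE)
  }))
  list(table = tab, by_height_class = by_height)
}
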