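#' Fit a linear height-diameter model
#'
#' Ordinary least squares of total height (m) on DBH (cm), the model used to
#' impute heights for trees whose height was not measured in the field (only
#' the tallest few trees per plot typically are). RMSE is
#' `sqrt(mean(residual^2))` on the fitting data.
#'
#' @param trees tree records; only rows with a measured height are used
#'   (column `height_is_measured` when present, otherwise non-missing
#'   `height`).
#' @return a `height_model` with `intercept` (m), `slope` (m/cm), `rmse` (m),
#'   `r2`, and `n`.
#' @export
fit_height_model <- function(trees) {
  use <- if ("height_is_measured" %in% names(trees)) {
    trees$height_is_measured & !is.na(trees$height)
  } else {
    !is.na(trees$height)
  }
  d <- trees[use, , drop = FALSE]
  if (nrow(d) < 3L) stop("need at least 3 trees with measured heights")
  if (stats::var(d$dbh) <= 0) stop("degenerate input: DBH has no variance")
  fit <- stats::lm(height ~ dbh, data = d)
  res <- stats::residuals(fit)
  structure(
    list(
      intercept = unname(stats::coef(fit)[1L]),
      slope = unname(stats::coef(fit)[2L]),
      rmse = sqrt(mean(res^2)),
      r2 = summary(fit)$r.squared,
      n = nrow(d)
    ),
    class = "height_model"
  )
}

#' @export
print.height_model <- function(x, ...) {
  cat(sprintf(
    "Height-DBH model: height = %.3f + %.4f * dbh  (n = %d, r2 = %.3f, RMSE = %.2f m)\n",
    x$intercept, x$slope, x$n, x$r2, x$rmse))
  invisible(x)
}

#' Impute missing tree heights, capped by the lidar pixel maximum
#'
#' Measured heights pass through unchanged. Missing heights are predicted
#' from the height-diameter model and, because the linear model over-predicts
#' for diameters beyond its calibration range, capped at the maximum lidar
#' return height of the 30 m pixel containing the plot (when available).
#' Capped predictions are floored just above breast height so downstream
#' volume models stay valid.
#'
#' @param trees tree record data.frame.
#' @param model a `height_model`.
#' @param pixel_max_height maximum lidar height of the containing pixel, m;
#'   scalar or one value per tree; `NULL` disables the cap (reported via a
#'   message).
#' @param force_predicted if TRUE, measured heights are also replaced by
#'   (capped) predictions — the sensitivity switch for testing the effect of
#'   height measurement.
#' @return the tree table with `height` filled and `height_is_measured`
#'   preserved.
#' @export
impute_height <- function(trees, model, pixel_max_height = NULL,
                          force_predicted = FALSE) {
  stopifnot(inherits(model, "height_model"))
  measured <- if ("height_is_measured" %in% names(trees)) {
    trees$height_is_measured & !is.na(trees$height)
  } else {
    !is.na(trees$height)
  }
  predicted <- model$intercept + model$slope * trees$dbh
  if (is.null(pixel_max_height)) {
    message("no pixel maximum height available; imputed heights are uncapped")
  } else {
    predicted <- pmin(predicted, pixel_max_height)
  }
  predicted <- pmax(predicted, BREAST_HEIGHT_M + 0.03)
  fill <- if (force_predicted) rep(TRUE, nrow(trees)) else !measured
  trees$height[fill] <- predicted[fill]
  trees$height_is_measured <- measured
  trees
}

#' Expand tree biomass to plot-level density (Bitterlich sampling)
#'
#' In a variable-radius (angle gauge) plot each counted tree represents
#' `baf / g` trees per hectare, where `g = pi * (dbh/200)^2` is its basal
#' area (m^2) and `baf` the basal-area factor (m^2/ha). A tree's contribution
#' to plot density is therefore `biomass_Mg * baf / g`, so large trees seen
#' from far away are down-weighted by their larger implicit plot area.
#'
#' @param biomass data.frame from [estimate_tree_list()] (needs `total` in kg
#'   and `dbh` in cm); may be empty.
#' @param baf basal-area factor, m^2/ha (> 0).
#' @return plot biomass density, Mg/ha.
#' @export
expand_to_density <- function(biomass, baf) {
  if (!is.numeric(baf) || length(baf) != 1L || baf <= 0) {
    stop("baf must be a single positive number (m^2/ha)")
  }
  if (nrow(biomass) == 0L) return(0)
  g <- pi * (biomass$dbh / 200)^2
  sum((biomass$total / KG_PER_MG) * baf / g)
}

#' Plot-level biomass density for every allometric family
#'
#' Convenience pipeline: per plot, impute missing heights (needed by the
#' CRM), run each family's allometric engine over the tree list, and expand
#' to Mg/ha with the plot's basal-area factor.
#'
#' @param plots plot table with `plot_id`, `baf` and optionally
#'   `pixel_max_height` (m, used as the imputation cap).
#' @param trees tree table with a `plot_id` column joining it to `plots`.
#' @param registry an `allometry_registry`.
#' @param families character vector of families to estimate.
#' @param height_model a `height_model`; fitted from the measured trees in
#'   `trees` when NULL and any height is missing.
#' @param force_predicted passed to [impute_height()].
#' @return data.frame with `plot_id` and one density column (Mg/ha) per
#'   family.
#' @export
estimate_plot_biomass <- function(plots, trees, registry,
                                  families = c("jenkins", "chojnacky", "crm"),
                                  height_model = NULL,
                                  force_predicted = FALSE) {
  families <- match.arg(families, c("jenkins", "chojnacky", "crm"),
                        several.ok = TRUE)
  if (is.null(height_model) &&
      (any(is.na(trees$height)) || force_predicted)) {
    height_model <- fit_height_model(trees)
  }
  out <- data.frame(plot_id = plots$plot_id, stringsAsFactors = FALSE)
  for (fam in families) out[[fam]] <- NA_real_
  for (i in seq_len(nrow(plots))) {
    pt <- trees[trees$plot_id == plots$plot_id[i], , drop = FALSE]
    if (nrow(pt) > 0L && !is.null(height_model) &&
        (any(is.na(pt$height)) || force_predicted)) {
      cap <- if ("pixel_max_height" %in% names(plots)) {
        plots$pixel_max_height[i]
      } else NULL
      if (!is.null(cap) && (is.na(cap) || cap <= 0)) cap <- NULL
      pt <- suppressMessages(
        impute_height(pt, height_model, pixel_max_height = cap,
                      force_predicted = force_predicted))
    }
    for (fam in families) {
      est <- estimate_tree_list(pt, fam, registry)
      out[[fam]][i] <- expand_to_density(est, plots$baf[i])
    }
  }
  out
}
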