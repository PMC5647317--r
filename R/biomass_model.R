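#' Random forest configuration
#'
#' Defaults follow standard random-forest regression practice for lidar
#' biomass modeling: 500 trees and 7 candidate predictors per split.
#'
#' @param n_trees number of trees in the ensemble.
#' @param mtry predictors tried at each split.
#' @param seed RNG seed, making the fit reproducible.
#' @return a `model_config` list.
#' @export
model_config <- function(n_trees = 500, mtry = 7, seed = 1) {
  stopifnot(n_trees >= 1, mtry >= 1)
  structure(list(n_trees = as.integer(n_trees), mtry = as.integer(mtry),
                 seed = as.integer(seed)),
            class = "model_config")
}

#' Filter spatial outlier plots before model fitting
#'
#' Two rules remove plots whose field estimate and lidar canopy obviously
#' disagree (canopy-mask failures over tall non-vegetated surfaces, or plot
#' geolocation error): (a) a tall lidar canopy (max height > 10 m) over a
#' field biomass of zero; (b) a very tall canopy (max height > 30 m) over a
#' small field estimate (< 50 Mg/ha). "Zero" biomass means below 1e-6 Mg/ha
#' to avoid floating-point equality.
#'
#' @param plot_data data.frame with one row per plot.
#' @param biomass_col name of the field biomass density column (Mg/ha).
#' @param height_col name of the maximum lidar height column (m).
#' @return list with `kept` (the retained rows), `removed` (the dropped rows
#'   with a `rule` column, `"zero_biomass_tall_lidar"` or
#'   `"low_biomass_very_tall_lidar"`), and `n_removed`.
#' @export
filter_plots <- function(plot_data, biomass_col = "biomass",
                         height_col = "zmax") {
  b <- plot_data[[biomass_col]]
  h <- plot_data[[height_col]]
  if (is.null(b) || is.null(h)) {
    stop("plot_data must contain columns '", biomass_col, "' and '",
         height_col, "'")
  }
  rule_a <- h > 10 & b < 1e-6
  rule_b <- !rule_a & b < 50 & h > 30
  removed <- plot_data[rule_a | rule_b, , drop = FALSE]
  if (nrow(removed) > 0L) {
    removed$rule <- ifelse(rule_a[rule_a | rule_b],
                           "zero_biomass_tall_lidar",
                           "low_biomass_very_tall_lidar")
  } else {
    removed$rule <- character(0)
  }
  list(
    kept = plot_data[!(rule_a | rule_b), , drop = FALSE],
    removed = removed,
    n_removed = nrow(removed)
  )
}

#' Fit a random-forest biomass model with out-of-bag diagnostics
#'
#' Models plot biomass density as a function of the lidar metric suite (and
#' any ancillary predictors). Fit quality is reported out-of-bag: each plot
#' is predicted only by ensemble trees whose bootstrap sample excluded it,
#' giving leakage-free residuals from a single fit.
#'
#' @param data data.frame with the response and predictor columns.
#' @param response name of the response column (Mg/ha).
#' @param predictors character vector of predictor column names; freezing the
#'   same set across allometric families isolates allometry as the only
#'   difference between their models.
#' @param config a [model_config()].
#' @param family optional label carried on the result.
#' @return a `biomass_rf` object: the fitted forest, observed and out-of-bag
#'   predicted densities, residuals (predicted - observed), `r2`, `rmse`,
#'   `pct_rmse` (100 * rmse / mean observed), a variable-importance ranking,
#'   and the configuration echo.
#' @export
fit_biomass_model <- function(data, response, predictors,
                              config = model_config(), family = response) {
  missing <- setdiff(c(response, predictors), names(data))
  if (length(missing) > 0L) {
    stop("data is missing column(s): ", paste(missing, collapse = ", "))
  }
  if (nrow(data) < 30L) {
    stop("need at least 30 plots to fit; got ", nrow(data))
  }
  x <- data[, predictors, drop = FALSE]
  y <- data[[response]]
  if (!all(stats::complete.cases(x)) || anyNA(y)) {
    stop("predictors and response must be complete")
  }
  mtry <- min(config$mtry, length(predictors))
  set.seed(config$seed)
  forest <- randomForest::randomForest(
    x = x, y = y, ntree = config$n_trees, mtry = mtry, importance = TRUE
  )
  predicted <- unname(forest$predicted)  # out-of-bag
  residuals <- predicted - y
  sst <- sum((y - mean(y))^2)
  r2 <- if (sst > 0) 1 - sum(residuals^2) / sst else 1
  rmse <- sqrt(mean(residuals^2))
  imp <- randomForest::importance(forest, type = 1L)
  ranking <- data.frame(
    predictor = rownames(imp),
    importance = imp[, 1L],
    stringsAsFactors = FALSE, row.names = NULL
  )
  ranking <- ranking[order(-ranking$importance), , drop = FALSE]
  structure(
    list(
      forest = forest, family = family, predictors = predictors,
      n_trees = config$n_trees, mtry = mtry, seed = config$seed,
      observed = y, predicted = predicted, residuals = residuals,
      r2 = r2, rmse = rmse,
      pct_rmse = 100 * rmse / mean(y),
      mean_residual = mean(residuals),
      importance = ranking
    ),
    class = "biomass_rf"
  )
}

#' @export
print.biomass_rf <- function(x, ...) {
  cat(sprintf("Random-forest biomass model (%s): %d trees, mtry %d, n = %d\n",
              x$family, x$n_trees, x$mtry, length(x$observed)))
  cat(sprintf("  out-of-bag r2 = %.3f, RMSE = %.1f Mg/ha (%.0f%%), mean residual = %.2f\n",
              x$r2, x$rmse, x$pct_rmse, x$mean_residual))
  cat("  top predictors:",
      paste(utils::head(x$importance$predictor, 5L), collapse = ", "), "\n")
  invisible(x)
}

#' Mean model residual by height class and biomass class
#'
#' Stratifies out-of-bag residuals into the canopy-height classes 0-10,
#' 10-25, 25-40, 40-55, > 55 m and the biomass classes 0-100, 100-200,
#' 200-300, 300-400, > 400 Mg/ha, reporting the mean residual and count per
#' class plus the overall mean. Classes with no plots are absent from the
#' output rather than reported as zero.
#'
#' @param fit a `biomass_rf`, or a numeric vector of residuals
#'   (predicted - observed).
#' @param heights maximum lidar height per plot, m.
#' @param observed observed biomass per plot, Mg/ha (defaults to the fit's).
#' @return data.frame with `class_type` (`"height"`, `"biomass"`,
#'   `"overall"`), `class`, `n`, `mean_residual`.
#' @export
residuals_by_class <- function(fit, heights, observed = NULL) {
  if (inherits(fit, "biomass_rf")) {
    residuals <- fit$residuals
    if (is.null(observed)) observed <- fit$observed
  } else {
    residuals <- fit
    if (is.null(observed)) stop("observed biomass required")
  }
  stopifnot(length(heights) == length(residuals),
            length(observed) == length(residuals))
  height_cls <- cut(heights, breaks = c(0, 10, 25, 40, 55, Inf),
                    labels = c("0-10 m", "10-25 m", "25-40 m", "40-55 m",
                               "> 55 m"),
                    include.lowest = TRUE, right = TRUE)
  biomass_cls <- cut(observed, breaks = c(0, 100, 200, 300, 400, Inf),
                     labels = c("0-100 Mg/ha", "100-200 Mg/ha",
                                "200-300 Mg/ha", "300-400 Mg/ha",
                                "> 400 Mg/ha"),
                     include.lowest = TRUE, right = TRUE)
  summarize <- function(cls, type) {
    present <- levels(cls)[levels(cls) %in% as.character(unique(cls))]
    do.call(rbind, lapply(present, function(lv) {
      sel <- !is.na(cls) & cls == lv
      data.frame(class_type = type, class = lv, n = sum(sel),
                 mean_residual = mean(residuals[sel]),
                 stringsAsFactors = FALSE)
    }))
  }
  rbind(
    summarize(height_cls, "height"),
    summarize(biomass_cls, "biomass"),
    data.frame(class_type = "overall", class = "all", n = length(residuals),
               mean_residual = mean(residuals), stringsAsFactors = FALSE)
  )
}
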