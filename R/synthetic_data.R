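#' Configuration for the synthetic inventory + lidar generator
#'
#' Defines the study conditions the generator emulates: a 179-plot
#' variable-radius inventory stratified into short (< 5 m), medium (5-25 m)
#' and tall (> 25 m) forest, an FIA-like linear height-diameter relation with
#' residual scatter of 5.85 m, lidar point clouds at a nominal density of
#' 10.66 returns/m^2, 13 contaminated plots (9 with a tall canopy over zero
#' field biomass, 4 with a very tall canopy over a small field estimate — the
#' geolocation-error stand-ins removed by [filter_plots()], taking 179 plots
#' to 166), and a county pixel population with known true biomass.
#'
#' @param seed integer RNG seed; the same configuration always yields
#'   identical output.
#' @param n_plots number of field plots.
#' @param n_empty_contaminated plots given zero biomass but a tall swapped-in
#'   canopy (filter rule a).
#' @param n_low_contaminated plots given < 50 Mg/ha biomass but a > 30 m
#'   swapped-in canopy (filter rule b).
#' @param strata_props named proportions for short/medium/tall strata
#'   (must sum to 1).
#' @param baf basal-area factor of the variable-radius plots, m^2/ha.
#' @param footprint_radius lidar extraction radius around plot centroids, m.
#' @param returns_per_m2 nominal lidar return density.
#' @param cloud_noise_sd vertical jitter of canopy returns, m.
#' @param height_truth list `intercept` (m), `slope` (m/cm), `sd` (m): the
#'   true height-diameter law used for FIA-like tree generation.
#' @param county list `n_pixels`, `forest_fraction`, `points_per_pixel`
#'   controlling the county population.
#' @return a `synth_config` list.
#' @export
synth_config <- function(seed = 1,
                         n_plots = 179,
                         n_empty_contaminated = 9,
                         n_low_contaminated = 4,
                         strata_props = c(short = 0.25, medium = 0.40,
                                          tall = 0.35),
                         baf = 2,
                         footprint_radius = 15,
                         returns_per_m2 = 10.66,
                         cloud_noise_sd = 0.5,
                         height_truth = list(intercept = 6, slope = 0.55,
                                             sd = 5.85),
                         county = list(n_pixels = 2000,
                                       forest_fraction = 0.85,
                                       points_per_pixel = 150)) {
  if (abs(sum(strata_props) - 1) > 1e-8) stop("strata_props must sum to 1")
  if (height_truth$sd < 0 || cloud_noise_sd < 0) stop("sds must be >= 0")
  if (height_truth$slope <= 0) stop("height slope must be positive")
  structure(
    list(seed = as.integer(seed), n_plots = n_plots,
         n_empty_contaminated = n_empty_contaminated,
         n_low_contaminated = n_low_contaminated,
         strata_props = strata_props, baf = baf,
         footprint_radius = footprint_radius,
         returns_per_m2 = returns_per_m2,
         cloud_noise_sd = cloud_noise_sd,
         height_truth = height_truth, county = county),
    class = "synth_config"
  )
}

#' The frozen 40-predictor set
#'
#' 31 lidar metrics from [compute_metrics()] plus 9 ancillary covariates
#' (topography and composition). All allometric families are modeled on this
#' identical set so allometry is the only difference between their models.
#'
#' @return character vector of 40 predictor names.
#' @export
default_predictors <- function() {
  pcts <- seq(10, 90, by = 10)
  c("zmax", "zmean", "zq", paste0("p", pcts),
    paste0("b", c(2, 5, 10, 20, 30, 40, 50)), "cover", "density",
    "imean", paste0("ip", pcts),
    "elevation", "slope", "aspect_ns", "aspect_ew", "conifer_frac",
    "hardwood_frac", "dist_water", "soil_depth", "ndvi")
}

# ancillary covariates shared by the plot and pixel generators; `size` in
# [0, 1] scales composition covariates with stand stature
ancillary_covariates <- function(n, size) {
  theta <- stats::runif(n, 0, 2 * pi)
  conifer <- pmin(1, pmax(0, 0.2 + 0.6 * size + stats::rnorm(n, 0, 0.15)))
  data.frame(
    elevation = stats::runif(n, 50, 800),
    slope = stats::runif(n, 0, 40),
    aspect_ns = cos(theta),
    aspect_ew = sin(theta),
    conifer_frac = conifer,
    hardwood_frac = pmax(0, 1 - conifer - stats::runif(n, 0, 0.3)),
    dist_water = stats::runif(n, 0, 5000),
    soil_depth = stats::runif(n, 20, 200),
    ndvi = pmin(0.95, pmax(0.05, 0.3 + 0.35 * size + stats::rnorm(n, 0, 0.1)))
  )
}

species_for_stratum <- function(stratum) {
  switch(stratum,
         short = c("ARME", "QUAG", "UMCA", "ALRU2"),
         medium = c("PSME", "QUAG", "QUKE", "UMCA", "ARME", "ACMA3", "LIDE3"),
         tall = c("PSME", "SESE3", "ABCO", "TSHE", "PIPO", "LIDE3"))
}

#' Generate an FIA-like tree table for height-model calibration
#'
#' Draws stems with lognormal diameters (truncated to the measurable range)
#' and heights that follow the configured linear height-diameter truth with
#' Gaussian residual scatter, emulating the regional inventory data a
#' height-imputation model would be calibrated on.
#'
#' @param config a [synth_config()].
#' @param n number of trees.
#' @return tree record data.frame (all heights measured) with the generating
#'   residual sd recoverable by [fit_height_model()].
#' @export
generate_fia_trees <- function(config, n = 2000) {
  stopifnot(inherits(config, "synth_config"))
  set.seed(config$seed)
  ht <- config$height_truth
  dbh <- stats::rlnorm(n, meanlog = log(30), sdlog = 0.55)
  out_of_range <- dbh < 12.7 | dbh > 250
  while (any(out_of_range)) {
    dbh[out_of_range] <- stats::rlnorm(sum(out_of_range), log(30), 0.55)
    out_of_range <- dbh < 12.7 | dbh > 250
  }
  height <- ht$intercept + ht$slope * dbh + stats::rnorm(n, 0, ht$sd)
  too_low <- height <= BREAST_HEIGHT_M + 0.1
  while (any(too_low)) {
    height[too_low] <- ht$intercept + ht$slope * dbh[too_low] +
      stats::rnorm(sum(too_low), 0, ht$sd)
    too_low <- height <= BREAST_HEIGHT_M + 0.1
  }
  species <- sample(c("PSME", "SESE3", "ABCO", "TSHE", "PIPO", "QUAG", "QUKE",
                      "UMCA", "ARME", "LIDE3", "ACMA3", "ALRU2"),
                    n, replace = TRUE,
                    prob = c(25, 8, 6, 5, 6, 14, 8, 9, 7, 6, 3, 3))
  tree_records(species, dbh, height)
}

# one plot's tree list, drawn per stratum; distances follow Bitterlich
# inclusion (proportional-to-basal-area), capped so the sampled stand lies
# inside the lidar footprint
simulate_plot_trees <- function(stratum, kind, baf, ht) {
  n <- switch(kind,
              empty = 0L,
              low = 1L + stats::rpois(1L, 1.2),
              natural = switch(stratum,
                               short = stats::rpois(1L, 3),
                               medium = 1L + stats::rpois(1L, 8),
                               tall = max(stats::rpois(1L, 15), 8L)))
  if (n == 0L) {
    return(data.frame(species_code = character(0), dbh = numeric(0),
                      height_true = numeric(0), distance = numeric(0),
                      stringsAsFactors = FALSE))
  }
  if (kind == "low") {
    dbh <- stats::runif(n, 4, 8)
    height <- stats::runif(n, 1.6, 4.2)
  } else if (stratum == "short") {
    dbh <- stats::runif(n, 3, 8)
    height <- stats::runif(n, 1.5, 4.5)
  } else if (stratum == "medium") {
    dbh <- stats::runif(n, 10, 35)
    height <- pmin(pmax(ht$intercept + ht$slope * dbh + stats::rnorm(n, 0, 2),
                        5.5), 24.5)
  } else {
    top_height <- stats::runif(1L, 28, 55)  # site-dependent stand top height
    dbh <- stats::runif(n, 35, 110)
    height <- pmin(pmax(ht$intercept + ht$slope * dbh + stats::rnorm(n, 0, 3),
                        26), top_height)
  }
  r_incl <- pmin(dbh / (2 * sqrt(baf)), 13)
  data.frame(
    species_code = sample(species_for_stratum(stratum), n, replace = TRUE),
    dbh = dbh,
    height_true = height,
    distance = sqrt(stats::runif(n)) * r_incl,
    stringsAsFactors = FALSE
  )
}

# point cloud for one plot footprint: per-tree cone-surface sampling with
# Gaussian vertical jitter plus near-ground background returns; one return is
# pinned at each tree top so the cloud maximum tracks the tallest stem
simulate_cloud <- function(trees, centroid, config) {
  radius <- config$footprint_radius
  area <- pi * radius^2
  n_pts <- round(area * config$returns_per_m2)
  n_trees <- nrow(trees)
  if (n_trees > 0L) {
    crown_r <- pmax(0.8, 0.12 * trees$height_true)
    cover_frac <- min(0.92, sum(pi * crown_r^2) / area)
    n_canopy <- round(n_pts * cover_frac)
  } else {
    n_canopy <- 0L
  }
  theta_t <- stats::runif(max(n_trees, 1L), 0, 2 * pi)
  tx <- centroid[1L] + trees$distance * cos(theta_t[seq_len(n_trees)])
  ty <- centroid[2L] + trees$distance * sin(theta_t[seq_len(n_trees)])
  parts <- list()
  if (n_canopy > 0L) {
    idx <- sample.int(n_trees, n_canopy, replace = TRUE,
                      prob = crown_r^2)
    h <- trees$height_true[idx]
    z <- h - 0.45 * h * sqrt(stats::runif(n_canopy)) +
      stats::rnorm(n_canopy, 0, config$cloud_noise_sd)
    z <- pmin(pmax(z, 0.5), h)
    ang <- stats::runif(n_canopy, 0, 2 * pi)
    rad <- sqrt(stats::runif(n_canopy)) * crown_r[idx]
    px <- tx[idx] + rad * cos(ang)
    py <- ty[idx] + rad * sin(ang)
    d <- sqrt((px - centroid[1L])^2 + (py - centroid[2L])^2)
    shrink <- pmin(1, (radius - 0.1) / pmax(d, 1e-9))
    px <- centroid[1L] + (px - centroid[1L]) * shrink
    py <- centroid[2L] + (py - centroid[2L]) * shrink
    parts$canopy <- data.frame(
      x = px, y = py, z = z,
      intensity = stats::rgamma(n_canopy, shape = 4, scale = 30),
      return_number = 1L
    )
    # pin one return at each tree apex
    parts$tops <- data.frame(
      x = pmin(pmax(tx, centroid[1L] - radius + 0.1), centroid[1L] + radius - 0.1),
      y = pmin(pmax(ty, centroid[2L] - radius + 0.1), centroid[2L] + radius - 0.1),
      z = trees$height_true,
      intensity = stats::rgamma(n_trees, shape = 4, scale = 30),
      return_number = 1L
    )
  }
  n_ground <- max(n_pts - n_canopy, 20L)
  ang <- stats::runif(n_ground, 0, 2 * pi)
  rad <- sqrt(stats::runif(n_ground)) * radius
  parts$ground <- data.frame(
    x = centroid[1L] + rad * cos(ang),
    y = centroid[2L] + rad * sin(ang),
    z = abs(stats::rnorm(n_ground, 0, 0.2)),
    intensity = stats::rgamma(n_ground, shape = 2, scale = 15),
    return_number = sample(c(1L, 2L), n_ground, replace = TRUE,
                           prob = c(0.4, 0.6))
  )
  cloud <- do.call(rbind, parts)
  cloud$is_vegetation <- TRUE
  rownames(cloud) <- NULL
  cloud
}

#' Generate a stratified variable-radius inventory with per-plot point clouds
#'
#' Builds `n_plots` plots with per-stratum stem lists (diameters, true and
#' measured heights — only the tallest two trees per plot carry a measured
#' height, as in the emulated inventory), simulates a vegetation point cloud
#' per plot footprint, and injects contamination by swapping clouds between
#' plots: tall canopies are moved onto zero-biomass and low-biomass plots so
#' the configured numbers of plots trigger each outlier filter rule, standing
#' in for plot geolocation error.
#'
#' @param config a [synth_config()].
#' @return list with `plots` (plot_id, x, y, baf, stratum, pixel_max_height,
#'   ancillary covariates), `trees` (plot_id keyed tree records with
#'   `height_true` and `distance`), `clouds` (named list of return sets), and
#'   `contaminated` (plot_id + rule truth).
#' @export
generate_plots_and_clouds <- function(config) {
  stopifnot(inherits(config, "synth_config"))
  set.seed(config$seed + 1L)
  n <- config$n_plots
  props <- config$strata_props
  counts <- floor(props * n)
  counts[1L] <- counts[1L] + (n - sum(counts))
  strata <- sample(rep(names(props), counts))
  n_contam <- config$n_empty_contaminated + config$n_low_contaminated
  short_idx <- which(strata == "short")
  tall_idx <- which(strata == "tall")
  if (n_contam > 0L && length(short_idx) < n_contam) {
    stop("not enough short-stratum plots to host ", n_contam,
         " contaminated plots")
  }
  if (n_contam > 0L && length(tall_idx) < n_contam) {
    stop("not enough tall-stratum plots to donate canopies")
  }
  kind <- rep("natural", n)
  kind[short_idx[seq_len(config$n_empty_contaminated)]] <- "empty"
  kind[short_idx[config$n_empty_contaminated +
                   seq_len(config$n_low_contaminated)]] <- "low"

  plot_id <- sprintf("P%03d", seq_len(n))
  px <- seq_len(n) * 1000
  py <- rep(0, n)
  tree_list <- vector("list", n)
  clouds <- vector("list", n)
  for (i in seq_len(n)) {
    tl <- simulate_plot_trees(strata[i], kind[i], config$baf,
                              config$height_truth)
    tree_list[[i]] <- tl
    clouds[[i]] <- simulate_cloud(tl, c(px[i], py[i]), config)
  }
  names(clouds) <- plot_id

  contaminated <- data.frame(plot_id = character(0), rule = character(0),
                             stringsAsFactors = FALSE)
  if (n_contam > 0L) {
    cloud_max <- vapply(clouds, function(cl) max(cl$z), numeric(1L))
    donors <- tall_idx[order(-cloud_max[tall_idx])]
    targets_b <- which(kind == "low")
    targets_a <- which(kind == "empty")
    swap_pairs <- rbind(
      if (length(targets_b) > 0L)
        cbind(targets_b, donors[seq_along(targets_b)]),
      if (length(targets_a) > 0L)
        cbind(targets_a, donors[length(targets_b) + seq_along(targets_a)])
    )
    for (k in seq_len(nrow(swap_pairs))) {
      t_i <- swap_pairs[k, 1L]; d_i <- swap_pairs[k, 2L]
      tmp <- clouds[[t_i]]
      # re-center the donor cloud on the target footprint and vice versa
      clouds[[t_i]] <- recenter_cloud(clouds[[d_i]], c(px[d_i], py[d_i]),
                                      c(px[t_i], py[t_i]))
      clouds[[d_i]] <- recenter_cloud(tmp, c(px[t_i], py[t_i]),
                                      c(px[d_i], py[d_i]))
    }
    contaminated <- data.frame(
      plot_id = plot_id[c(targets_a, targets_b)],
      rule = c(rep("zero_biomass_tall_lidar", length(targets_a)),
               rep("low_biomass_very_tall_lidar", length(targets_b))),
      stringsAsFactors = FALSE
    )
  }

  trees <- do.call(rbind, lapply(seq_len(n), function(i) {
    tl <- tree_list[[i]]
    if (nrow(tl) == 0L) {
      return(data.frame(plot_id = character(0), species_code = character(0),
                        dbh = numeric(0), height = numeric(0),
                        height_is_measured = logical(0),
                        height_true = numeric(0), distance = numeric(0),
                        stringsAsFactors = FALSE))
    }
    measured <- rank(-tl$height_true, ties.method = "first") <= 2L
    data.frame(plot_id = plot_id[i], species_code = tl$species_code,
               dbh = tl$dbh,
               height = ifelse(measured, tl$height_true, NA_real_),
               height_is_measured = measured,
               height_true = tl$height_true, distance = tl$distance,
               stringsAsFactors = FALSE)
  }))
  rownames(trees) <- NULL

  mean_h <- vapply(tree_list, function(tl)
    if (nrow(tl) > 0L) mean(tl$height_true) else 0, numeric(1L))
  plots <- cbind(
    data.frame(plot_id = plot_id, x = px, y = py, baf = config$baf,
               stratum = strata,
               pixel_max_height = vapply(clouds, function(cl) max(cl$z),
                                         numeric(1L)),
               stringsAsFactors = FALSE),
    ancillary_covariates(n, pmin(1, mean_h / 40))
  )
  list(plots = plots, trees = trees, clouds = clouds,
       contaminated = contaminated)
}

recenter_cloud <- function(cloud, from, to) {
  cloud$x <- cloud$x - from[1L] + to[1L]
  cloud$y <- cloud$y - from[2L] + to[2L]
  cloud
}

#' Generate a county pixel population with known true biomass
#'
#' Draws a latent true biomass density per 30 m pixel from a right-skewed
#' mixture (most area in low and mid classes, a small fraction above 400
#' Mg/ha), then produces each forest pixel's lidar metrics from a small point
#' cloud whose canopy height and cover scale with the latent biomass — the
#' same cloud-to-metric pathway the plot generator uses. The recorded true
#' mean and total support estimator-recovery experiments.
#'
#' @param config a [synth_config()]; the `county` element controls size.
#' @return list with `pixels` (pixel_id, x, y, forest, true_agb, the
#'   40-predictor suite, n_returns), `true_mean` (Mg/ha over forest pixels),
#'   `true_total_mg`, and `area_ha`.
#' @export
generate_county <- function(config) {
  stopifnot(inherits(config, "synth_config"))
  set.seed(config$seed + 2L)
  cc <- config$county
  n <- cc$n_pixels
  forest <- stats::runif(n) < cc$forest_fraction
  comp <- sample.int(4L, n, replace = TRUE,
                     prob = c(0.40, 0.42, 0.13, 0.05))
  shape <- c(1.2, 6, 10, 14)[comp]
  mean_agb <- c(25, 150, 280, 378)[comp]
  agb <- stats::rgamma(n, shape = shape, scale = mean_agb / shape)
  agb[!forest] <- 0

  npp <- cc$points_per_pixel
  side <- ceiling(sqrt(n))
  metric_rows <- vector("list", n)
  for (i in seq_len(n)) {
    if (!forest[i] || agb[i] < 1e-9) {
      metric_rows[[i]] <- compute_metrics(
        data.frame(x = numeric(0), y = numeric(0), z = numeric(0),
                   intensity = numeric(0), is_vegetation = logical(0)))
      next
    }
    H <- 1.6 * agb[i]^0.58 * exp(stats::rnorm(1L, 0, 0.08))
    cover_frac <- agb[i] / (agb[i] + 60)
    n_canopy <- round(npp * cover_frac)
    n_ground <- npp - n_canopy
    z_can <- if (n_canopy > 0L) {
      zc <- H - 0.45 * H * sqrt(stats::runif(n_canopy)) +
        stats::rnorm(n_canopy, 0, 0.3)
      pmin(pmax(zc, 0.3), H)
    } else numeric(0)
    z <- c(z_can, if (n_canopy > 0L) H, abs(stats::rnorm(n_ground, 0, 0.2)))
    m <- length(z)
    metric_rows[[i]] <- compute_metrics(data.frame(
      x = stats::runif(m, 0, 30), y = stats::runif(m, 0, 30), z = z,
      intensity = stats::rgamma(m, shape = 3, scale = 25),
      return_number = sample(c(1L, 2L), m, replace = TRUE, prob = c(0.7, 0.3)),
      is_vegetation = TRUE
    ))
  }
  metrics <- do.call(rbind, metric_rows)
  pixels <- cbind(
    data.frame(pixel_id = seq_len(n),
               x = ((seq_len(n) - 1L) %% side) * 30,
               y = ((seq_len(n) - 1L) %/% side) * 30,
               forest = forest, true_agb = agb),
    metrics,
    ancillary_covariates(n, pmin(1, agb / 450))
  )
  list(
    pixels = pixels,
    true_mean = mean(agb[forest]),
    true_total_mg = sum(agb[forest]) * PIXEL_AREA_HA,
    area_ha = PIXEL_AREA_HA
  )
}
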