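make_small_fit <- function(seed = 3) {
  set.seed(seed)
  n <- 60
  dat <- data.frame(x1 = runif(n, 0, 40), x2 = runif(n), x3 = runif(n))
  dat$y <- 5 * dat$x1 + rnorm(n, 0, 10)
  fit_biomass_model(dat, "y", c("x1", "x2", "x3"),
                    model_config(n_trees = 150, mtry = 2, seed = seed))
}

test_that("map prediction is consistent with point predictions and the forest mask", {
  fit <- make_small_fit()
  set.seed(4)
  pixels <- data.frame(pixel_id = 1:100, x1 = runif(100, 0, 40),
                       x2 = runif(100), x3 = runif(100),
                       forest = rep(c(TRUE, FALSE), 50))
  map <- predict_map(fit, pixels)
  expect_true(all(is.na(map$density[!pixels$forest])))
  direct <- predict(fit$forest, newdata = pixels[pixels$forest, c("x1", "x2", "x3")])
  expect_equal(map$density[pixels$forest], unname(direct))

  # aggregation oracle: map mean equals the mean of per-pixel calls
  per_pixel <- vapply(which(pixels$forest), function(i) {
    unname(predict(fit$forest, newdata = pixels[i, c("x1", "x2", "x3")]))
  }, numeric(1))
  expect_equal(mean(map$density, na.rm = TRUE), mean(per_pixel))

  none <- transform(pixels, forest = FALSE)
  expect_true(all(is.na(predict_map(fit, none)$density)))

  expect_error(predict_map(fit, pixels[, c("pixel_id", "x1", "forest")]),
               "x2")
})

test_that("class distribution bins exhaustively and conserves the county total", {
  d <- c(10, 20, 49.9, 75, 150, 250, 320, 405, 500, NA)
  cd <- class_distribution(d, edges = c(0, 50, 100, 200, 300, 400))
  expect_equal(sum(cd$fraction), 1)
  expect_equal(cd$n, c(3L, 1L, 1L, 1L, 1L, 2L))
  expect_equal(sum(cd$total_mg), sum(d, na.rm = TRUE) * 0.09)

  # exhaustive binning oracle on each class
  edges <- c(0, 50, 100, 200, 300, 400, Inf)
  for (k in 1:6) {
    sel <- !is.na(d) & d >= edges[k] & d < edges[k + 1]
    expect_equal(cd$fraction[k], sum(sel) / 9)
    expect_equal(cd$total_mg[k], sum(d[sel]) * 0.09)
  }

  one <- class_distribution(rep(120, 7))
  expect_equal(one$fraction[one$class == "100-200"], 1)
  expect_error(class_distribution(d, edges = c(0, 50, 50)), "increasing")
})

test_that("the model-assisted estimator matches its formula and identities", {
  map <- c(90, 110, NA, 100)  # map mean 100 over forest pixels
  z <- ma_estimate(map, observed = c(0, 0, 0), predicted = c(10, -2, 4))
  expect_equal(z$map_mean, 100)
  expect_equal(z$ma_mean, 96)
  e <- c(10, -2, 4)
  expect_equal(z$se, sqrt(sum((e - mean(e))^2) / (3 * 2)))
  expect_equal(z$se, sqrt(12))
  expect_equal(z$total_mg, 100 * 3 * 0.09, tolerance = 1e-9)

  # zero residuals: the adjustment vanishes and the SE is exactly zero
  z0 <- ma_estimate(map, observed = c(5, 8), predicted = c(5, 8))
  expect_equal(z0$ma_mean, z0$map_mean)
  expect_equal(z0$se, 0)

  # adjustment direction: overprediction pulls the MA mean below the map mean
  zo <- ma_estimate(map, observed = c(10, 20), predicted = c(30, 25))
  expect_lt(zo$ma_mean, zo$map_mean)
  zu <- ma_estimate(map, observed = c(30, 25), predicted = c(10, 20))
  expect_gt(zu$ma_mean, zu$map_mean)

  expect_error(ma_estimate(map, observed = 5, predicted = 5), "at least 2")
})

test_that("family comparisons report differences, percent and significance", {
  cmp <- compare_families(
    totals = c(jenkins = 62.17e6, chojnacky = 61.72e6, crm = 51.62e6),
    means = c(jenkins = 145.2, chojnacky = 143.7, crm = 121.4),
    ses = c(jenkins = 7.13, chojnacky = 7.73, crm = 6.09)
  )
  jc <- cmp[cmp$family_a == "jenkins" & cmp$family_b == "crm", ]
  expect_equal(jc$diff_million_mg, 10.55, tolerance = 1e-9)
  expect_equal(jc$pct_diff, 100 * 10.55 / 51.62, tolerance = 1e-9)
  expect_true(jc$significant_at_95)

  jch <- cmp[cmp$family_b == "chojnacky", ]
  expect_lt(abs(jch$pct_diff), 1)
  expect_false(jch$significant_at_95)

  # antisymmetry up to a change of reference total
  ab <- compare_families(c(A = 10e6, B = 8e6))
  ba <- compare_families(c(B = 8e6, A = 10e6))
  expect_equal(ab$pct_diff, -ba$pct_diff * (10e6 / 8e6), tolerance = 1e-12)

  # identical estimates: zero difference, trivially non-significant
  same <- compare_families(c(A = 5e6, B = 5e6), means = c(A = 100, B = 100),
                           ses = c(A = 3, B = 3))
  expect_equal(same$pct_diff, 0)
  expect_equal(same$t, 0)
  expect_false(same$significant_at_95)

  # reference switch
  first <- compare_families(c(A = 12e6, B = 10e6), reference = "first")
  expect_equal(first$pct_diff, 100 * 2 / 12)
})

test_that("discrepancy diagnostics join families to lidar structure", {
  pd <- data.frame(plot_id = c("p1", "p2", "p3", "p4"),
                   jenkins = c(100, 200, 300, 150),
                   crm = c(90, 210, 250, 150))
  mt <- data.frame(plot_id = c("p1", "p2", "p3", "p4"),
                   zmax = c(8, 20, 35, 50), zmean = c(4, 12, 22, 30),
                   cover = c(30, 60, 85, 90))
  dd <- discrepancy_diagnostics(pd, mt)
  expect_named(dd$table, c("plot_id", "difference", "zmax", "zmean", "cover",
                           "mean_biomass"))
  expect_equal(dd$table$difference, c(-10, 10, -50, 0))
  expect_equal(dd$table$mean_biomass, c(95, 205, 275, 150))
  expect_equal(dd$by_height_class$mean_difference, c(-10, 10, -50, 0))

  same <- discrepancy_diagnostics(transform(pd, crm = jenkins), mt)
  expect_true(all(same$table$difference == 0))
  expect_error(discrepancy_diagnostics(pd[, c("plot_id", "jenkins")], mt),
               "crm")
})
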