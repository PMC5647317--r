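test_that("generation is fully deterministic under a fixed seed", {
  cfg <- synth_config(seed = 33, n_plots = 40, n_empty_contaminated = 2,
                      n_low_contaminated = 1,
                      county = list(n_pixels = 30, forest_fraction = 0.8,
                                    points_per_pixel = 40))
  expect_identical(generate_fia_trees(cfg, 200), generate_fia_trees(cfg, 200))
  s1 <- generate_plots_and_clouds(cfg)
  s2 <- generate_plots_and_clouds(cfg)
  expect_identical(s1$trees, s2$trees)
  expect_identical(s1$plots, s2$plots)
  expect_identical(s1$clouds, s2$clouds)
  expect_identical(generate_county(cfg)$pixels, generate_county(cfg)$pixels)
})

test_that("FIA-like trees follow the configured height law", {
  cfg0 <- synth_config(seed = 2, height_truth = list(intercept = 6,
                                                     slope = 0.55, sd = 0))
  t0 <- generate_fia_trees(cfg0, 300)
  expect_equal(t0$height, 6 + 0.55 * t0$dbh, tolerance = 1e-12)
  expect_true(all(t0$dbh > 0))
  expect_true(all(t0$height > 1.37))

  # refit recovers slope and intercept within two standard errors
  cfg <- synth_config(seed = 8)
  tr <- generate_fia_trees(cfg, 2000)
  fit <- lm(height ~ dbh, data = tr)
  se <- coef(summary(fit))[, "Std. Error"]
  expect_lt(abs(coef(fit)[["(Intercept)"]] - 6), 2 * se[1])
  expect_lt(abs(coef(fit)[["dbh"]] - 0.55), 2 * se[2])
})

test_that("generated plots satisfy the upstream type invariants", {
  cfg <- synth_config(seed = 14)
  sim <- generate_plots_and_clouds(cfg)
  expect_equal(nrow(sim$plots), 179L)
  expect_true(all(sim$trees$dbh > 0))
  expect_true(all(is.na(sim$trees$height) | sim$trees$height > 1.37))
  expect_true(all(sim$plots$baf > 0))
  expect_true(all(vapply(sim$clouds, function(cl) all(cl$z >= 0), logical(1))))
  expect_setequal(unique(sim$plots$stratum), c("short", "medium", "tall"))
  # at most the two tallest stems per plot carry a measured height
  per_plot <- tapply(sim$trees$height_is_measured, sim$trees$plot_id, sum)
  expect_true(all(per_plot <= 2))
})

test_that("cloud maxima track the tallest generated stem when uncontaminated", {
  cfg <- synth_config(seed = 5, n_plots = 30, n_empty_contaminated = 0,
                      n_low_contaminated = 0)
  sim <- generate_plots_and_clouds(cfg)
  for (pid in unique(sim$trees$plot_id)) {
    tallest <- max(sim$trees$height_true[sim$trees$plot_id == pid])
    expect_equal(max(sim$clouds[[pid]]$z), tallest, tolerance = 1e-9)
  }
  # no contamination -> the outlier filters remove nothing
  reg <- default_registry()
  pm <- plot_metric_table(sim$clouds, sim$plots)
  pb <- estimate_plot_biomass(sim$plots, sim$trees, reg,
                              height_model = make_height_model(6, 0.55))
  dat <- merge(pb, pm, by = "plot_id")
  dat$biomass <- dat$jenkins
  expect_equal(filter_plots(dat)$n_removed, 0L)
})

test_that("the engineered contamination drives the 179 to 166 plot count", {
  cfg <- synth_config(seed = 11)
  sim <- generate_plots_and_clouds(cfg)
  expect_equal(nrow(sim$contaminated), 13L)
  reg <- default_registry()
  pm <- plot_metric_table(sim$clouds, sim$plots)
  pb <- estimate_plot_biomass(sim$plots, sim$trees, reg,
                              height_model = make_height_model(6, 0.55))
  dat <- merge(pb, pm, by = "plot_id")
  dat$biomass <- dat$jenkins
  fl <- filter_plots(dat)
  expect_equal(nrow(fl$kept), 166L)
  expect_setequal(fl$removed$plot_id, sim$contaminated$plot_id)
  expect_equal(sum(fl$removed$rule == "zero_biomass_tall_lidar"), 9L)
  expect_equal(sum(fl$removed$rule == "low_biomass_very_tall_lidar"), 4L)
})

test_that("the county population has known truth and a low-biomass-dominated shape", {
  cfg1 <- synth_config(seed = 19, county = list(n_pixels = 1,
                                                forest_fraction = 1,
                                                points_per_pixel = 50))
  cty1 <- generate_county(cfg1)
  expect_equal(cty1$true_total_mg, cty1$pixels$true_agb[1] * 0.09)

  cfg <- synth_config(seed = 20)
  cty <- generate_county(cfg)
  agb <- cty$pixels$true_agb[cty$pixels$forest]
  expect_lt(mean(agb > 400), 0.10)        # small high-biomass tail
  expect_gt(mean(agb < 300), 0.5)         # most area in low/mid classes
  expect_equal(cty$true_mean, mean(agb))
  expect_true(all(complete.cases(cty$pixels[, default_predictors()])))
})

test_that("truth coefficients reproduce plot densities that biased ones miss", {
  reg <- toy_registry()
  # a deliberately biased registry: intercepts shifted up by 0.4 on log scale
  reg_biased <- toy_registry(b0 = c(g1 = -1.6, g2 = -1.1))
  trees <- tree_records(c("AAA", "BBB", "AAA"), c(20, 30, 45),
                        height = c(15, 20, 28))
  trees$plot_id <- "p1"
  plots <- data.frame(plot_id = "p1", baf = 2)
  truth <- estimate_plot_biomass(plots, trees, reg, families = "jenkins")
  biased <- estimate_plot_biomass(plots, trees, reg_biased,
                                  families = "jenkins")
  expect_equal(biased$jenkins / truth$jenkins, exp(0.4), tolerance = 1e-9)
  expect_gt(abs(biased$jenkins - truth$jenkins), 0)
})
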