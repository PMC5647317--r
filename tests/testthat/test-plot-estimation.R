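test_that("height model recovers an exact line and matches hand OLS", {
  trees <- tree_records(rep("AAA", 4), c(10, 20, 30, 40),
                        height = 1.37 + 0.5 * c(10, 20, 30, 40))
  m <- suppressWarnings(fit_height_model(trees))  # lm warns on a perfect fit
  expect_equal(m$intercept, 1.37, tolerance = 1e-10)
  expect_equal(m$slope, 0.5, tolerance = 1e-10)
  expect_equal(m$rmse, 0, tolerance = 1e-8)
  expect_equal(m$r2, 1, tolerance = 1e-10)

  # 3-point normal equations by hand: dbh {10,20,30}, h {10,14,21}
  # slope = Sxy/Sxx = 110/200, intercept = 15 - slope*20
  t3 <- tree_records(rep("AAA", 3), c(10, 20, 30), height = c(10, 14, 21))
  m3 <- fit_height_model(t3)
  expect_equal(m3$slope, 110 / 200, tolerance = 1e-12)
  expect_equal(m3$intercept, 15 - (110 / 200) * 20, tolerance = 1e-12)
  fitted <- m3$intercept + m3$slope * c(10, 20, 30)
  expect_equal(m3$rmse, sqrt(mean((c(10, 14, 21) - fitted)^2)),
               tolerance = 1e-12)
  expect_equal(m3$r2, 1 - sum((c(10, 14, 21) - fitted)^2) / 62,
               tolerance = 1e-12)

  expect_error(fit_height_model(tree_records(rep("A", 3), c(10, 10, 10),
                                             height = c(9, 10, 11))),
               "variance")
  expect_error(fit_height_model(tree_records("A", 10, height = 9)),
               "at least 3")
})

test_that("height imputation passes measured heights, caps predictions, and is idempotent", {
  m <- make_height_model(1.37, 0.5)
  trees <- data.frame(species_code = "AAA", dbh = 50, height = 41.2,
                      height_is_measured = TRUE)
  expect_equal(impute_height(trees, m, 30)$height, 41.2)

  t2 <- data.frame(species_code = "AAA", dbh = 10, height = NA_real_,
                   height_is_measured = FALSE)
  expect_equal(impute_height(t2, m, 100)$height, 6.37)

  # over-prediction capped at the pixel maximum
  m_big <- make_height_model(0, 1)
  t3 <- data.frame(species_code = "AAA", dbh = 80, height = NA_real_,
                   height_is_measured = FALSE)
  expect_equal(impute_height(t3, m_big, pixel_max_height = 62)$height, 62)

  once <- impute_height(t3, m_big, 62)
  twice <- impute_height(once, m_big, 62)
  expect_equal(once, twice)

  # the cap applies only to imputed heights, not measured ones
  expect_equal(impute_height(trees, m_big, 5)$height, 41.2)

  expect_message(impute_height(t2, m, pixel_max_height = NULL), "uncapped")
})

test_that("Bitterlich expansion matches brute-force per-tree summation", {
  empty <- data.frame(dbh = numeric(0), total = numeric(0))
  expect_equal(expand_to_density(empty, baf = 2), 0)

  # one tree whose implicit plot area is 0.05 ha: g/baf = 0.05 -> g = 0.1 m^2
  d <- 200 * sqrt(0.1 / pi)
  one <- data.frame(dbh = d, total = 500)  # 0.5 Mg
  expect_equal(expand_to_density(one, baf = 2), 10, tolerance = 1e-10)

  # three-tree toy plot vs independent hand computation
  toy <- data.frame(dbh = c(15, 30, 55), total = c(60, 420, 2100))
  hand <- sum((toy$total / 1000) * 2 / (pi * (toy$dbh / 200)^2))
  expect_equal(expand_to_density(toy, baf = 2), hand, tolerance = 1e-12)

  # linearity in biomass and proportionality in BAF
  expect_equal(expand_to_density(transform(toy, total = 2 * total), 2),
               2 * expand_to_density(toy, 2))
  expect_equal(expand_to_density(toy, 4), 2 * expand_to_density(toy, 2))

  expect_error(expand_to_density(toy, baf = 0), "positive")
})

test_that("per-tree family ordering propagates to plot density", {
  set.seed(5)
  dbh <- runif(8, 10, 60)
  a <- data.frame(dbh = dbh, total = exp(-2 + 2.4 * log(dbh)))
  b <- data.frame(dbh = dbh, total = exp(-2.3 + 2.4 * log(dbh)))
  expect_true(all(a$total >= b$total))
  expect_gte(expand_to_density(a, 2), expand_to_density(b, 2))
})

test_that("plot pipeline imputes heights then expands every family", {
  reg <- toy_registry()
  plots <- data.frame(plot_id = c("p1", "p2"), baf = 2,
                      pixel_max_height = c(35, 28))
  trees <- data.frame(
    plot_id = c("p1", "p1", "p2"),
    species_code = c("AAA", "BBB", "AAA"),
    dbh = c(30, 18, 42),
    height = c(22, NA, NA),
    height_is_measured = c(TRUE, FALSE, FALSE),
    stringsAsFactors = FALSE
  )
  hm <- make_height_model(2, 0.6)
  pb <- estimate_plot_biomass(plots, trees, reg, height_model = hm)
  expect_named(pb, c("plot_id", "jenkins", "chojnacky", "crm"))
  expect_true(all(pb$jenkins > 0 & pb$crm > 0))

  # jenkins density equals manual expansion of the per-tree engine
  co <- lookup_coefficients(reg, c("AAA", "BBB"), "jenkins")
  t1 <- trees[trees$plot_id == "p1", ]
  manual <- sum(exp(co$b0 + co$b1 * log(t1$dbh)) / 1000 * 2 /
                  (pi * (t1$dbh / 200)^2))
  expect_equal(pb$jenkins[pb$plot_id == "p1"], manual, tolerance = 1e-12)

  # density is zero iff the tree list is empty
  pb0 <- estimate_plot_biomass(data.frame(plot_id = "p3", baf = 2),
                               trees[0, ], reg)
  expect_equal(pb0$jenkins, 0)
})
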