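# toy two-species registry built in code; chojnacky coefficients deliberately
# identical to jenkins group-for-group so family-agreement structure is testable
toy_registry <- function(b0 = c(g1 = -2.0, g2 = -1.5),
                         b1 = c(g1 = 2.4, g2 = 2.2),
                         dbh_max = c(g1 = 60, g2 = 40),
                         chojnacky_equal = TRUE) {
  species <- data.frame(
    species_code = c("AAA", "BBB"),
    jenkins_group = c("g1", "g2"),
    chojnacky_group = c("g1", "g2"),
    wood_specific_gravity = c(0.45, 0.6),
    stringsAsFactors = FALSE
  )
  lnln_rows <- function(fam, shift = 0) {
    do.call(rbind, lapply(names(b0), function(g) {
      data.frame(family = fam, group_id = g,
                 parameter = c("b0", "b1", "dbh_max_sampled"),
                 value = c(b0[[g]] + shift, b1[[g]], dbh_max[[g]]),
                 stringsAsFactors = FALSE)
    }))
  }
  crm_rows <- do.call(rbind, lapply(names(b0), function(g) {
    data.frame(family = "crm", group_id = g,
               parameter = c("vol_a", "vol_b", "bark_r0", "bark_r1",
                             "branch_r0", "branch_r1", "specific_gravity"),
               value = c(0, 0.002, 0.2, -0.1, 0.3, -0.05, 0.5),
               stringsAsFactors = FALSE)
  }))
  coeffs <- rbind(lnln_rows("jenkins"),
                  lnln_rows("chojnacky", shift = if (chojnacky_equal) 0 else 0.4),
                  crm_rows)
  read_coefficient_registry(coeffs, species)
}

# hand-constructed height model, bypassing fitting
make_height_model <- function(intercept, slope, rmse = 0, r2 = 1, n = 3) {
  structure(list(intercept = intercept, slope = slope, rmse = rmse,
                 r2 = r2, n = n), class = "height_model")
}

random_cloud <- function(n, zmax = 40, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  data.frame(
    x = runif(n, -20, 20), y = runif(n, -20, 20),
    z = runif(n, 0, zmax),
    intensity = rgamma(n, 3, scale = 20),
    is_vegetation = TRUE
  )
}
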