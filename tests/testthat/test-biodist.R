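test_that("SUV and %IA/g conversions are exact inverses", {
  expect_equal(suv_from_pct_ia_per_g(5, 25), 1.25)
  expect_equal(suv_from_pct_ia_per_g(0, 73000), 0)
  x <- c(0.3, 1.7, 4.2)
  expect_equal(pct_ia_per_g_from_suv(suv_from_pct_ia_per_g(x, 27.3), 27.3), x,
               tolerance = 1e-12)
  expect_error(suv_from_pct_ia_per_g(-1, 25), class = "predose_validation_error")
  expect_error(suv_from_pct_ia_per_g(1, 0), class = "predose_validation_error")
})

test_that("volume concentrations divide by tissue density", {
  expect_equal(concentration_from_volume(2, 1), 2)
  expect_equal(concentration_from_volume(2, 1.05), 2 / 1.05)
  expect_equal(concentration_from_volume(0, 1.05), 0)
  expect_error(concentration_from_volume(2, 0), class = "predose_validation_error")
})

test_that("replicate aggregation computes per-animal SUV means and sample SDs", {
  df <- data.frame(region = "Liver", time_h = 1, replicate = 1:2,
                   value = c(1, 3), unit = "suv", body_mass_g = 25)
  s <- aggregate_suv(df)
  expect_equal(s$mean_suv, 2)
  expect_equal(s$sd_suv, sqrt(2))
  expect_equal(s$n, 2L)

  one <- aggregate_suv(df[1, ])
  expect_equal(one$mean_suv, 1)
  expect_equal(one$sd_suv, 0)

  # per-animal body masses enter through the SUV conversion
  df2 <- data.frame(region = "Liver", time_h = 1, replicate = 1:2,
                    value = c(4, 6), unit = "pct_ia_per_g",
                    body_mass_g = c(20, 30))
  expect_equal(aggregate_suv(df2)$mean_suv, mean(c(0.8, 1.8)))
  # population-mean-mass approximation differs, and is flagged
  s3 <- aggregate_suv(df2, use_mean_mass = TRUE)
  expect_equal(s3$mean_suv, mean(c(4, 6) * 25 / 100))
  expect_true(s3$meta$mean_mass)

  mixed <- rbind(df, within(df, region <- "Kidneys"))
  expect_error(aggregate_suv(mixed), class = "predose_validation_error")
  bad <- within(df, unit <- "becquerel")
  expect_error(aggregate_suv(bad), class = "predose_validation_error")
})

test_that("aggregation is invariant to the input unit and to shared masses", {
  set.seed(42)
  times <- c(1, 4, 24)
  df_pct <- expand.grid(time_h = times, replicate = 1:3)
  df_pct$region <- "Liver"
  df_pct$value <- runif(nrow(df_pct), 0.5, 6)
  df_pct$unit <- "pct_ia_per_g"
  df_pct$body_mass_g <- runif(nrow(df_pct), 20, 30)
  df_suv <- df_pct
  df_suv$value <- suv_from_pct_ia_per_g(df_pct$value, df_pct$body_mass_g)
  df_suv$unit <- "suv"
  a <- aggregate_suv(df_pct)
  b <- aggregate_suv(df_suv)
  expect_equal(a$mean_suv, b$mean_suv, tolerance = 1e-12)
  expect_equal(a$sd_suv, b$sd_suv, tolerance = 1e-12)

  # equal body masses: per-animal and mean-mass aggregation coincide
  df_eq <- df_pct
  df_eq$body_mass_g <- 25
  expect_equal(aggregate_suv(df_eq)$mean_suv,
               aggregate_suv(df_eq, use_mean_mass = TRUE)$mean_suv,
               tolerance = 1e-12)
})

test_that("carcass route assembles the mass-weighted total-body SUV", {
  ph <- phantom("toy", 25,
                data.frame(region = c("Organ", "Carc"), mass_g = c(5, 20),
                           is_source = TRUE, is_target = TRUE))
  carc <- concentration_series("Carc", c(1, 2), c(0.5, 0.4))
  org <- concentration_series("Organ", c(1, 2), c(2.0, 1.0))
  tb <- total_body_from_carcass(carc, list(org), ph)
  expect_equal(tb$region, "Totalbody")
  expect_equal(tb$mean_suv, c((0.5 * 20 + 2 * 5) / 25, (0.4 * 20 + 1 * 5) / 25))

  # no excised organs: carcass is the whole body (up to the mass audit)
  ph2 <- phantom("toy2", 25, data.frame(region = "Carc", mass_g = 24.99,
                                        is_source = TRUE, is_target = TRUE))
  tb2 <- total_body_from_carcass(carc, list(), ph2)
  expect_equal(tb2$mean_suv, carc$mean_suv * 24.99 / 25)

  expect_error(total_body_from_carcass(carc, list(org, org), ph),
               "more than once", class = "predose_validation_error")
  ph3 <- phantom("toy3", 25,
                 data.frame(region = c("Organ", "Carc"), mass_g = c(5, 18),
                            is_source = TRUE, is_target = TRUE))
  expect_warning(total_body_from_carcass(carc, list(org), ph3),
                 class = "predose_mass_mismatch")
})

test_that("whole-body reading ratios pass through as decay-uncorrected fractions", {
  r <- data.frame(time_h = c(0, 6), reading = c(200, 100))
  tas <- total_body_from_ratios(r)
  expect_s3_class(tas, "predose_tas")
  expect_equal(tas$a, c(1, 0.5))

  up <- data.frame(time_h = c(0, 2), reading = c(100, 120))
  expect_warning(tas2 <- total_body_from_ratios(up),
                 class = "predose_fraction_gt_one")
  expect_equal(tas2$a[2], 1.2)  # retained, not clipped

  expect_error(total_body_from_ratios(data.frame(time_h = numeric(),
                                                 reading = numeric())),
               class = "predose_validation_error")
  expect_error(total_body_from_ratios(data.frame(time_h = 2, reading = 50)),
               "time-0", class = "predose_validation_error")
})
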