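test_that("clustered household sampling honours the survey design", {
  cfg <- synth_config(n_clusters = 249, households_per_cluster = 53, seed = 4)
  hh <- sample_households(cfg, seed = 4)
  expect_equal(nrow(hh$households), 13197)
  expect_equal(sort(unique(hh$households$cluster_id)), 1:249)
  # every household within its cluster radius and inside the region
  d <- sqrt((hh$households$x - hh$centers[hh$households$cluster_id, 1])^2 +
            (hh$households$y - hh$centers[hh$households$cluster_id, 2])^2)
  expect_true(all(d <= cfg$cluster_radius + 1e-12))
  expect_true(all(hh$households$x >= 0 & hh$households$x <= 600))
  expect_true(all(hh$households$y >= 0 & hh$households$y <= 150))
  # zero answer prevalence gives all-zero binary covariates
  cfg0 <- synth_config(n_clusters = 5, households_per_cluster = 10,
                       answer_prevalence = c(food_storage = 0,
                                             straw_storage = 0,
                                             sleep_floor = 0,
                                             animal_shed = 0), seed = 1)
  hh0 <- sample_households(cfg0, seed = 1)
  expect_true(all(hh0$households[c("food_storage", "straw_storage",
                                   "sleep_floor", "animal_shed")] == 0))
  expect_error(synth_config(region_extent = c(2, 2), cluster_radius = 1.5),
               "cluster_radius")
})

test_that("covariate surfaces stay inside their configured ranges", {
  cfg <- synth_config(n_clusters = 5, households_per_cluster = 5,
                      region_extent = c(100, 60), seed = 2)
  surf <- generate_covariate_surfaces(cfg, seed = 2)
  bio6 <- surf$rasters$bio6$values
  expect_gte(min(bio6), 1.8)
  expect_lte(max(bio6), 10.9)
  bio17 <- surf$rasters$bio17$values
  expect_gte(min(bio17), 18)
  expect_lte(max(bio17), 71)
  expect_true(all(surf$rasters$ndvi$values >= 0 &
                  surf$rasters$ndvi$values <= 1))
  expect_true(all(surf$rasters$pig_density$values >= 0))
  # smoothness 0: unfiltered white noise, in range and uncorrelated
  cfg0 <- synth_config(n_clusters = 5, households_per_cluster = 5,
                       region_extent = c(200, 200),
                       surface_smoothness_km = 0, seed = 3)
  surf0 <- generate_covariate_surfaces(cfg0, seed = 3)
  v <- as.vector(surf0$rasters$ndvi$values)
  expect_true(all(v >= 0 & v <= 1))
  lag1 <- cor(v[-1], v[-length(v)])
  expect_lt(abs(lag1), 0.05)
})

test_that("outcomes follow the hierarchical logistic model", {
  dat <- survey_data(5, n_clusters = 40, households_per_cluster = 25,
                     extent = c(200, 100))
  sv <- dat$survey
  # intercept driven to -50: no cases at all
  cfg <- synth_config(n_clusters = 40, households_per_cluster = 25,
                      region_extent = c(200, 100), intercept = -50,
                      outcome_prevalence_target = NULL, seed = 5)
  out <- generate_outcomes(sv$households, sv$design, cfg, seed = 5,
                           centers = sv$centers)
  expect_true(all(out$outcome == 0))
  # no field, zero effects, zero intercept: symmetric coin
  cfg2 <- synth_config(n_clusters = 40, households_per_cluster = 25,
                       region_extent = c(200, 100), spatial_sd = 0,
                       true_beta = c(ndvi = 0), intercept = 0,
                       outcome_prevalence_target = NULL, seed = 6)
  out2 <- generate_outcomes(sv$households, sv$design, cfg2, seed = 6)
  n <- length(out2$outcome)
  expect_lt(abs(mean(out2$outcome) - 0.5), 3 * sqrt(0.25 / n))
  expect_identical(out2$u, numeric(n))
  # a coefficient name absent from the design is rejected
  cfg3 <- synth_config(true_beta = c(not_a_covariate = 1), seed = 1)
  expect_error(generate_outcomes(sv$households, sv$design, cfg3, seed = 1),
               "missing from design")
})

test_that("prevalence calibration hits the published rate at survey size", {
  cfg <- synth_config(seed = 10)   # full defaults: 13,197 households, 1.18%
  sv <- simulate_survey(cfg)
  n <- nrow(sv$households)
  se <- sqrt(0.0118 * (1 - 0.0118) / n)
  expect_lt(abs(mean(sv$households$outcome) - 0.0118), 3 * se)
  # calibration is on the realized mean risk, exactly
  expect_equal(mean(plogis(sv$truth$eta)), 0.0118, tolerance = 1e-8)
})

test_that("identical config and seed reproduce a bit-identical survey", {
  cfg <- synth_config(n_clusters = 12, households_per_cluster = 8,
                      region_extent = c(80, 50), seed = 21)
  a <- simulate_survey(cfg)
  b <- simulate_survey(cfg)
  expect_identical(a$households, b$households)
  expect_identical(a$design, b$design)
  expect_identical(a$truth$u, b$truth$u)
  expect_identical(lapply(a$rasters, `[[`, "values"),
                   lapply(b$rasters, `[[`, "values"))
})
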