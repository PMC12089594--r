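test_that("default design matches the study layout", {
  des <- default_cohort_design()
  expect_equal(des$n_batches, 30L)
  expect_equal(des$container_split[["syringe"]], 17L)
  expect_equal(des$container_split[["vial"]], 13L)
  expect_length(des$type_labels, 9L)
  expect_equal(des$temperature_set, c(5, 25, 37))
  expect_equal(design_record_count(des, use_training_grid = TRUE), 2160L)
  expect_equal(design_record_count(des),
               30L * 9L * (9L + 5L + 4L))
})

test_that("design constructor enforces its invariants", {
  expect_error(cohort_design(n_batches = 30L,
                             container_split = c(syringe = 10L, vial = 10L)),
               "sum to n_batches")
  expect_error(cohort_design(training_grid = list(`5` = c(0, 40),
                                                  `25` = c(1, 3),
                                                  `37` = c(1, 3))),
               "training_grid")
})

test_that("generator config rejects unphysical settings", {
  expect_error(generator_config(residual_sd = -1), "standard deviations")
  expect_error(generator_config(taper_rate = -0.1), "taper_rate")
  # degradation must not decelerate with temperature
  expect_error(generator_config(slope_mean_by_temp = c(`5` = -1, `25` = -0.5,
                                                       `37` = -2)),
               "non-increasing")
  expect_error(generator_config(slope_mean_by_temp = c(`5` = 0.1, `25` = -1,
                                                       `37` = -2)))
})

test_that("sample_true_parameters is seed-deterministic and layered", {
  p1 <- sample_true_parameters(seed = 11L)
  p2 <- sample_true_parameters(seed = 11L)
  expect_identical(p1, p2)
  expect_false(identical(p1, sample_true_parameters(seed = 12L)))

  # degenerate layers: zero type-level spread collapses types
  cfg0 <- generator_config(type_intercept_sd = 0, type_slope_sd = 0)
  p0 <- sample_true_parameters(cfg0, seed = 5L)
  expect_true(all(p0$type_intercepts == 0))
  for (tp in colnames(p0$type_slope_means)) {
    expect_true(all(p0$type_slope_means[, tp] ==
                      p0$slope_mean_by_temp[[tp]]))
  }

  # Monte-Carlo check of the type layer spread at large n_types
  des500 <- cohort_design(n_batches = 2L,
                          container_split = c(vial = 2L),
                          type_labels = sprintf("T%03d", 1:500))
  p500 <- sample_true_parameters(generator_config(), des500, seed = 21L)
  sd37 <- stats::sd(p500$type_slope_means[, "37"])
  expect_lt(abs(sd37 - generator_config()$type_slope_sd),
            3 * generator_config()$type_slope_sd / sqrt(2 * 499))
})

test_that("simulate_dataset produces the declared mean structure", {
  des1 <- cohort_design(n_batches = 1L, container_split = c(vial = 1L),
                        type_labels = "A")
  # sigma = 0, kappa = 0, no batch/type spread: exact lines per temperature
  cfg <- generator_config(type_intercept_sd = 0, batch_intercept_sd = 0,
                          type_slope_sd = 0, batch_slope_sd = 0,
                          residual_sd = 0)
  p <- sample_true_parameters(cfg, des1, seed = 1L)
  ds <- simulate_dataset(p, des1, seed = 2L)
  for (tp in c(5, 25, 37)) {
    sub <- ds[ds$temperature_C == tp, ]
    slope <- diff(sub$potency[1:2]) / diff(sub$time_months[1:2])
    expect_equal(slope, unname(cfg$slope_mean_by_temp[as.character(tp)]),
                 tolerance = 1e-10)
    expect_equal(sub$potency,
                 100 + slope * sub$time_months, tolerance = 1e-10)
  }

  # taper reduces total loss: potency at 36 months above the linear value
  cfg_t <- generator_config(type_intercept_sd = 0, batch_intercept_sd = 0,
                            type_slope_sd = 0, batch_slope_sd = 0,
                            residual_sd = 0, taper_rate = 0.05)
  ds_t <- simulate_dataset(sample_true_parameters(cfg_t, des1, seed = 1L),
                           des1, seed = 2L)
  at36 <- function(d) d$potency[d$temperature_C == 5 & d$time_months == 36]
  expect_gt(at36(ds_t), at36(ds))

  # determinism
  p_def <- sample_true_parameters(seed = 3L, design = small_design())
  expect_identical(
    as.data.frame(simulate_dataset(p_def, small_design(), seed = 4L)),
    as.data.frame(simulate_dataset(p_def, small_design(), seed = 4L)))

  # temperature ordering of the expected monthly drop (noise-free truth)
  tm <- attr(ds, "true_means")
  drop_per_month <- sapply(c(5, 25, 37), function(tp) {
    sub <- which(ds$temperature_C == tp & ds$time_months > 0)
    mean((100 - tm[sub]) / ds$time_months[sub])
  })
  expect_true(all(diff(drop_per_month) > 0))
})

test_that("residual variance fraction behaves at its limits", {
  params <- sample_true_parameters(seed = 5L, design = small_design())
  # sigma = 0: the true mean explains everything
  cfg0 <- generator_config(residual_sd = 0)
  p0 <- sample_true_parameters(cfg0, small_design(), seed = 5L)
  ds0 <- simulate_dataset(p0, small_design(), seed = 6L)
  rv0 <- residual_variance_fraction(ds0, fit = attr(ds0, "true_means"))
  expect_equal(rv0$fraction, 0, tolerance = 1e-10)

  # pure noise: constant truth, noise only -> fraction near 1
  cfg1 <- generator_config(type_intercept_sd = 0, batch_intercept_sd = 0,
                           type_slope_sd = 0, batch_slope_sd = 0,
                           residual_sd = 4,
                           slope_mean_by_temp = c(`5` = 0, `25` = 0,
                                                  `37` = 0))
  p1 <- sample_true_parameters(cfg1, small_design(), seed = 7L)
  ds1 <- simulate_dataset(p1, small_design(), seed = 8L)
  rv1 <- residual_variance_fraction(ds1, fit = attr(ds1, "true_means"))
  expect_gt(rv1$fraction, 0.9)

  expect_error(residual_variance_fraction(
    stability_dataset(tiny_records()[1, ])), "fewer than 2")
})

test_that("default cohort noise share matches the analytic share", {
  cfg <- generator_config()
  des <- default_cohort_design()
  p <- sample_true_parameters(cfg, des, seed = 31L)
  ds <- simulate_dataset(p, des, seed = 32L)
  rv <- residual_variance_fraction(ds)
  # analytic share: sigma^2 over (sigma^2 + variance of the batch/type mean
  # structure about the pooled structure), computed from the known truth
  tm <- attr(ds, "true_means")
  g <- stats::lm.fit(bayesstab:::taper_free_design(as.data.frame(ds)), tm)
  struct_var <- sum(g$residuals^2) / (nrow(ds) - g$rank)
  analytic <- cfg$residual_sd^2 / (cfg$residual_sd^2 + struct_var)
  expect_lt(abs(rv$fraction - analytic), 0.05)
  # assay noise is batch-independent: per-batch variances homogeneous
  expect_lt(rv$homogeneity_ratio, 2.0)
})

test_that("arrhenius slope parameterization matches the closed form", {
  sl <- arrhenius_slope_means(5e13, 80, c(5, 25, 37, 42))
  R <- 8.31446e-3
  expect_equal(unname(sl["25"]), -5e13 * exp(-80 / (R * 298.15)))
  expect_true(all(diff(sl) < 0))  # faster degradation when warmer
  expect_true(all(sl < 0))
  # usable as generator input
  cfg <- generator_config(slope_mean_by_temp = sl[c("5", "25", "37")])
  expect_s3_class(cfg, "generator_config")
})
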