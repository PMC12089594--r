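# Sampler verification against the closed-form conjugate oracle, parameter
# recovery, prediction intervals, shelf life.

test_that("closed-form oracle reproduces its analytic limits", {
  x <- c(0, 1, 2, 3, 6, 9, 12)
  y_line <- 100 - 0.8 * x
  orc <- closed_form_posterior_oracle(x, y_line)
  ols <- stats::lm.fit(cbind(1, x), y_line)$coefficients
  expect_equal(unname(orc$coef_mean), unname(ols), tolerance = 1e-5)

  # dogmatic prior pulls the posterior mean to the prior mean (zero)
  dog <- closed_form_posterior_oracle(
    x, y_line, prior_config(mean_prior_variance = 1e-9))
  expect_lt(max(abs(dog$coef_mean)), 1e-3)

  # consistency at n = 1e4
  set.seed(99)
  xx <- runif(1e4, 0, 36)
  yy <- 100 - 0.8 * xx + rnorm(1e4, 0, 4)
  big <- closed_form_posterior_oracle(xx, yy)
  expect_equal(unname(big$coef_mean[["slope"]]), -0.8, tolerance = 0.01)

  expect_error(closed_form_posterior_oracle(rep(2, 5), rnorm(5)),
               "rank error")
})

test_that("Gibbs posterior matches the oracle on single-group data", {
  set.seed(123)
  x <- rep(c(0, 1, 2, 3, 6, 9, 12, 18, 24, 36), each = 6)
  y <- 100 - 0.6 * x + rnorm(length(x), 0, 3)
  ds <- stability_dataset(data.frame(
    batch_id = "B1", molecular_type = "A", container = "vial",
    temperature_C = 5, time_months = x, potency = y))
  draws <- fit_gibbs(ds, mcmc = mcmc_config(n_iterations = 5000L,
                                            burn_in = 1000L, seed = 7L,
                                            n_chains = 1L))
  orc <- closed_form_posterior_oracle(x, y)
  g_int <- draws$alpha_bt[, 1]
  g_slp <- draws$beta_btT[, 1]
  expect_lt(abs(mean(g_int) - orc$coef_mean[["intercept"]]),
            3 * mcse(g_int))
  expect_lt(abs(mean(g_slp) - orc$coef_mean[["slope"]]),
            3 * mcse(g_slp))
  # posterior spread: vague-prior semi-conjugate vs NIG agree to O(p/n)
  expect_equal(stats::sd(g_int), orc$coef_sd[["intercept"]],
               tolerance = 0.1)
  expect_equal(stats::sd(g_slp), orc$coef_sd[["slope"]], tolerance = 0.1)
  expect_equal(mean(draws$variances[, "sigma2"]), orc$sigma2_mean,
               tolerance = 0.1)

  # predictive quantiles at 30 months vs the Student-t predictive
  iv <- predictive_interval(draws, list(batch_id = "B1",
                                        molecular_type = "A",
                                        container = "vial",
                                        temperature_C = 5,
                                        time_months = 30),
                            alpha = 0.05, seed = 11L)
  expect_equal(iv$lower, orc$predictive_quantile(30, 0.025),
               tolerance = 0.02 * abs(orc$predictive_quantile(30, 0.025)))
  expect_equal(iv$upper, orc$predictive_quantile(30, 0.975),
               tolerance = 0.02 * abs(orc$predictive_quantile(30, 0.975)))
})

test_that("noise-free lines give a concentrated, exact posterior", {
  ds <- line_dataset(intercept = 100, slope = -1)
  draws <- fit_gibbs(ds, mcmc = fast_mcmc())
  expect_equal(mean(draws$beta_btT[, 1]), -1, tolerance = 1e-3)
  expect_lt(stats::sd(draws$beta_btT[, 1]), 1e-2)
})

test_that("sampler is seed-deterministic and validates inputs", {
  ds <- stability_dataset(tiny_records())
  d1 <- fit_gibbs(ds, mcmc = fast_mcmc(seed = 9L))
  d2 <- fit_gibbs(ds, mcmc = fast_mcmc(seed = 9L))
  expect_identical(d1$beta_btT, d2$beta_btT)
  expect_identical(d1$variances, d2$variances)
  expect_equal(length(d1$mu_alpha), 1100L)  # (1500 - 400) x 1 chain

  # rank deficiency: one time point in a (type, temperature) stratum
  rec <- tiny_records()
  rec <- rec[!(rec$temperature_C == 25 & rec$time_months > 0), ]
  rec <- rec[rec$molecular_type == "A" | rec$temperature_C == 5, ]
  expect_error(fit_gibbs(stability_dataset(rec)),
               "rank-deficiency.*25")
  expect_error(fit_gibbs(stability_dataset(tiny_records()[0, ])), "empty")
})

test_that("global slope means and variances are recovered on the cohort", {
  cfg <- generator_config()
  p <- sample_true_parameters(cfg, seed = 51L)
  ds <- simulate_dataset(p, seed = 52L, use_training_grid = TRUE)
  draws <- fit_gibbs(ds, mcmc = fast_mcmc(seed = 53L))
  for (tp in c("5", "25", "37")) {
    err <- abs(mean(draws$M_T[, tp]) - cfg$slope_mean_by_temp[[tp]])
    expect_lt(err, 3 * stats::sd(draws$M_T[, tp]))
  }
  s2 <- draws$variances[, "sigma2"]
  expect_lt(abs(mean(s2) - cfg$residual_sd^2), 3 * stats::sd(s2))
})

test_that("prediction intervals nest and center correctly", {
  p <- sample_true_parameters(seed = 61L, design = small_design())
  ds <- simulate_dataset(p, small_design(), seed = 62L)
  draws <- fit_gibbs(ds, mcmc = fast_mcmc(seed = 63L))
  target <- list(batch_id = "new-batch", molecular_type = "A",
                 container = "syringe", temperature_C = 5, time_months = 0)
  # t = 0 mean-profile center: posterior mean of mu_alpha-level intercept
  iv <- predictive_interval(draws, target, kind = "mean_profile",
                            seed = 64L)
  expect_equal(iv$center,
               mean(draws$a_type[, "A"] + draws$gamma_syringe),
               tolerance = 0.05)
  iv01 <- predictive_interval(draws, target, alpha = 0.01, seed = 65L)
  iv05 <- predictive_interval(draws, target, alpha = 0.05, seed = 65L)
  expect_lt(iv01$lower, iv05$lower)
  expect_gt(iv01$upper, iv05$upper)
  # mean-profile band is narrower than the predictive band
  ivm <- predict_intervals(draws, as.data.frame(target),
                           kind = "mean_profile")
  expect_lt(ivm$upper - ivm$lower, iv05$upper - iv05$lower)

  expect_error(predictive_interval(draws, modifyList(target,
                                                     list(temperature_C = 42))),
               "extrapolation error")
  expect_error(predictive_interval(draws, modifyList(target,
                                                     list(batch_id = "ZZ"))),
               "not seen")
})

test_that("interval inflation scales the spread about the center", {
  draws <- fit_gibbs(stability_dataset(tiny_records()),
                     mcmc = fast_mcmc(seed = 19L))
  target <- data.frame(batch_id = "B1", molecular_type = "A",
                       container = "vial", temperature_C = 5,
                       time_months = 12)
  base <- predict_intervals(draws, target, seed = 3L)
  draws2 <- draws
  draws2$priors$interval_inflation <- 2
  wide <- predict_intervals(draws2, target, seed = 3L)
  expect_equal(wide$upper - wide$lower, 2 * (base$upper - base$lower),
               tolerance = 1e-10)
  expect_equal(wide$center, base$center)
})

test_that("shelf life follows its closed-form crossing on exact data", {
  # flat truth: slope 0, limit far below -> horizon
  flat <- line_cohort(intercept = 100, slope = 0)
  d_flat <- fit_gibbs(flat, mcmc = fast_mcmc(seed = 71L))
  expect_equal(as.numeric(estimate_shelf_life(d_flat, "A", "vial",
                                              spec_limit = 50,
                                              seed = 72L)), 48)
  # limit above the t = 0 lower bound -> 0
  expect_equal(as.numeric(estimate_shelf_life(d_flat, "A", "vial",
                                              spec_limit = 150,
                                              seed = 73L)), 0)
  # noise-free slope -2 from 100, limit 89: crossing at 5.5 -> floor 5
  ds <- line_cohort(intercept = 100, slope = -2)
  d <- fit_gibbs(ds, mcmc = fast_mcmc(seed = 74L))
  expect_equal(as.numeric(estimate_shelf_life(d, "A", "vial",
                                              spec_limit = 89,
                                              seed = 75L)),
               floor((89 - 100) / -2))
  expect_error(estimate_shelf_life(structure(list(mu_alpha = numeric(0)),
                                             class = "posterior_draws"),
                                   "A"), "empty draws")
})

test_that("posterior summary nests credible levels and bounds variances", {
  draws <- fit_gibbs(stability_dataset(tiny_records()),
                     mcmc = fast_mcmc(seed = 81L))
  s95 <- posterior_summary(draws, 0.95)
  s50 <- posterior_summary(draws, 0.50)
  expect_identical(s95$parameter, s50$parameter)
  expect_true(all(s95$lower <= s50$lower & s50$upper <= s95$upper))
  vr <- s95[s95$parameter %in% c("tau_a2", "sigma_a2", "tau_b2",
                                 "sigma_b2", "sigma2"), ]
  expect_equal(nrow(vr), 5L)
  expect_true(all(vr$lower > 0))
})

test_that("batch slopes shrink between the stratum OLS and the type mean", {
  # 3 batches, 1 type, few noisy points: partial pooling
  set.seed(42)
  times <- c(0, 3, 6)
  rec <- do.call(rbind, lapply(1:3, function(b) {
    data.frame(batch_id = paste0("B", b), molecular_type = "A",
               container = "vial", temperature_C = 5, time_months = times,
               potency = 100 + (b - 2) * 0.3 - (0.5 + 0.2 * b) * times +
                 rnorm(3, 0, 2))
  }))
  ds <- stability_dataset(rec)
  draws <- fit_gibbs(ds, mcmc = fast_mcmc(seed = 91L))
  type_mean <- mean(draws$m_tT[, 1])
  for (b in 1:3) {
    idx <- which(draws$btT_levels ==
                   paste(paste0("B", b), "A", "5", sep = "\r"))
    sub <- rec[rec$batch_id == paste0("B", b), ]
    ols <- stats::lm.fit(cbind(1, sub$time_months), sub$potency)$coefficients[2]
    post <- mean(draws$beta_btT[, idx])
    lo <- min(ols, type_mean) - 0.02
    hi <- max(ols, type_mean) + 0.02
    expect_gte(post, lo); expect_lte(post, hi)
  }
})

test_that("Arrhenius-tied slopes permit temperature extrapolation", {
  cfg <- generator_config(
    slope_mean_by_temp = arrhenius_slope_means(2e12, 80),
    type_slope_sd = 0.02, batch_slope_sd = 0.01)
  p <- sample_true_parameters(cfg, small_design(), seed = 101L)
  ds <- simulate_dataset(p, small_design(), seed = 102L,
                         use_training_grid = TRUE)
  draws <- fit_gibbs(ds, spec = model_spec("arrhenius"),
                     mcmc = fast_mcmc(seed = 103L))
  # draws honor the kinetic constraint exactly
  R <- 8.31446e-3
  M_from_pars <- -exp(draws$arrhenius[, "log_A"] -
                        draws$arrhenius[, "Ea_kJ"] / (R * (25 + 273.15)))
  expect_equal(unname(draws$M_T[, "25"]), unname(M_from_pars),
               tolerance = 1e-12)
  # prediction at an unseen temperature no longer errors
  iv42 <- predictive_interval(draws, list(batch_id = "new-batch",
                                          molecular_type = "A",
                                          container = "vial",
                                          temperature_C = 42,
                                          time_months = 3),
                              seed = 104L)
  expect_true(is.finite(iv42$lower) && iv42$lower < iv42$center)
  # the extrapolated slope is steeper than at 37 C on average
  expect_lt(mean(-exp(draws$arrhenius[, "log_A"] -
                        draws$arrhenius[, "Ea_kJ"] / (R * 315.15))),
            mean(draws$M_T[, "37"]))
})

test_that("saved draws reload into an equivalent predictor", {
  draws <- fit_gibbs(stability_dataset(tiny_records()),
                     mcmc = fast_mcmc(seed = 111L))
  dir <- withr::local_tempdir()
  save_posterior_draws(draws, dir)
  back <- load_posterior_draws(dir)
  target <- data.frame(batch_id = "B2", molecular_type = "B",
                       container = "syringe", temperature_C = 25,
                       time_months = 9)
  iv1 <- predict_intervals(draws, target, seed = 5L)
  iv2 <- predict_intervals(back, target, seed = 5L)
  expect_equal(iv1$lower, iv2$lower, tolerance = 1e-9)
  expect_equal(iv1$upper, iv2$upper, tolerance = 1e-9)
  expect_equal(back$batch_container, draws$batch_container)
})
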