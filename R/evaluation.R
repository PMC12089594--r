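# Validation machinery: empirical interval coverage, MSE by molecular type,
# time-split validation, the simulation benchmark (hierarchical vs per-batch
# linear vs mixed-effects), data-requirement curves and prior-sensitivity
# scans.

obs_key <- function(df) {
  paste(df$batch_id, df$molecular_type, df$temperature_C, df$time_months,
        sep = "\r")
}

# pair intervals/predictions with observations by coordinates; returns
# indices such that intervals[i_int, ] matches observations[i_obs, ]
pair_by_coordinates <- function(intervals, observations) {
  ki <- obs_key(intervals)
  ko <- obs_key(observations)
  oi <- order(ki); oo <- order(ko)
  if (length(ki) != length(ko) || !identical(ki[oi], ko[oo])) {
    stop("pairing error: interval and observation coordinates do not match",
         call. = FALSE)
  }
  list(i_int = oi, i_obs = oo)
}

#' Empirical coverage of prediction intervals
#'
#' The fraction of held-out observations falling inside their matched
#' interval (closed: points exactly on a bound count as covered).
#'
#' @param intervals a `prediction_interval` data.frame (one row per
#'   observation, matched by coordinates).
#' @param observations a [stability_dataset()] (or data.frame) with the
#'   same coordinates and a `potency` column.
#' @param model_name label recorded in the report.
#' @return object of class `coverage_report`: model name, alpha, counts,
#'   and the empirical coverage fraction.
#' @export
empirical_coverage <- function(intervals, observations,
                               model_name = "model") {
  observations <- as.data.frame(observations)
  p <- pair_by_coordinates(intervals, observations)
  pot <- observations$potency[p$i_obs]
  lo <- intervals$lower[p$i_int]
  hi <- intervals$upper[p$i_int]
  covered <- pot >= lo & pot <= hi
  structure(list(model_name = model_name,
                 alpha = intervals$alpha[1L],
                 n_points = length(covered),
                 n_covered = sum(covered),
                 empirical_coverage = mean(covered),
                 temperatures = sort(unique(observations$temperature_C)),
                 containers = sort(unique(observations$container))),
            class = "coverage_report")
}

#' @export
print.coverage_report <- function(x, ...) {
  cat(sprintf(
    "<coverage_report> %s | nominal %.0f%% | empirical %.1f%% (%d/%d)\n",
    x$model_name, 100 * (1 - x$alpha), 100 * x$empirical_coverage,
    x$n_covered, x$n_points))
  invisible(x)
}

#' Mean squared prediction error, overall and by molecular type
#'
#' @param predictions a `prediction_interval` data.frame (its `center` is
#'   the point prediction) or any data.frame with coordinates and `center`.
#' @param observations matching records with `potency`.
#' @return list with `overall` (pooled MSE) and `by_type` (named vector).
#' @export
prediction_mse_by_type <- function(predictions, observations) {
  observations <- as.data.frame(observations)
  p <- pair_by_coordinates(predictions, observations)
  err <- observations$potency[p$i_obs] - predictions$center[p$i_int]
  types <- observations$molecular_type[p$i_obs]
  list(overall = mean(err^2),
       by_type = tapply(err^2, types, mean) |> c())
}

# fit + 95%-style predictive intervals for one model name, shared by the
# validation harnesses
fit_and_predict <- function(model, train, test, alpha, priors, mcmc,
                            pred_seed = NULL) {
  if (model == "hierarchical") {
    draws <- fit_gibbs(train, priors = priors, mcmc = mcmc)
    lapply_alpha <- function(a) {
      predict_intervals(draws, test, alpha = a, kind = "predictive",
                        seed = pred_seed)
    }
  } else if (model == "linear") {
    fit <- fit_perbatch_linear(train)
    fitted_keys <- names(fit$strata)
    keep <- stratum_key(test$batch_id, test$molecular_type) %in% fitted_keys
    test <- test[keep, , drop = FALSE]
    lapply_alpha <- function(a) predict_linear(fit, test, alpha = a)
  } else if (model == "mixed") {
    fit <- fit_mixed_model(train)
    lapply_alpha <- function(a) predict_mixed(fit, test, alpha = a)
  } else {
    stop("unknown model: ", model, call. = FALSE)
  }
  list(test = test,
       intervals = stats::setNames(lapply(alpha, lapply_alpha),
                                   as.character(alpha)))
}

#' Time-split validation
#'
#' Trains every model on the records with `time <= cutoff` (all
#' temperatures) and evaluates interval coverage and MSE on the later
#' records, mimicking prospective use: predict long-term stability from
#' early time points.
#'
#' @param ds a [stability_dataset()].
#' @param cutoff training cutoff in months (default 6).
#' @param models subset of `c("hierarchical", "linear", "mixed")`.
#' @param alphas miscoverage levels evaluated.
#' @param holdout_temperature optional temperature restriction of the test
#'   split (e.g. 5 for the long-term storage condition).
#' @param priors,mcmc hierarchical-model settings.
#' @return list of class `time_split_report`: `coverage` (one row per model
#'   and alpha), `mse` (per model overall), `mse_by_type` (long), and the
#'   split sizes.
#' @export
run_time_split_validation <- function(ds, cutoff = 6,
                                      models = c("hierarchical", "linear",
                                                 "mixed"),
                                      alphas = c(0.01, 0.05, 0.1),
                                      holdout_temperature = NULL,
                                      priors = prior_config(),
                                      mcmc = mcmc_config()) {
  sp <- split_by_time(ds, cutoff, holdout_temperature)
  if (nrow(sp$test) == 0L) {
    stop("split error: no records after cutoff ", cutoff, " months",
         call. = FALSE)
  }
  coverage <- list(); mse_rows <- list(); mse_type_rows <- list()
  for (model in models) {
    fp <- tryCatch(
      fit_and_predict(model, sp$train, sp$test, alphas, priors, mcmc,
                      pred_seed = mcmc$seed + 7919L),
      error = function(e) stop("model '", model, "': ", conditionMessage(e),
                               call. = FALSE))
    for (a in names(fp$intervals)) {
      cr <- empirical_coverage(fp$intervals[[a]], fp$test, model)
      coverage[[length(coverage) + 1L]] <- data.frame(
        model = model, alpha = as.numeric(a),
        n_points = cr$n_points, n_covered = cr$n_covered,
        empirical_coverage = cr$empirical_coverage)
    }
    m <- prediction_mse_by_type(fp$intervals[[1L]], fp$test)
    mse_rows[[model]] <- data.frame(model = model, mse = m$overall)
    mse_type_rows[[model]] <- data.frame(model = model,
                                         molecular_type = names(m$by_type),
                                         mse = unname(m$by_type))
  }
  structure(list(coverage = do.call(rbind, coverage) |>
                   `rownames<-`(NULL),
                 mse = do.call(rbind, unname(mse_rows)) |> `rownames<-`(NULL),
                 mse_by_type = do.call(rbind, unname(mse_type_rows)) |>
                   `rownames<-`(NULL),
                 n_train = nrow(sp$train), n_test = nrow(sp$test),
                 cutoff = cutoff),
            class = "time_split_report")
}

#' Simulation scenario specification
#'
#' One cell of the benchmark design: a dataset setting (full cohort,
#' syringe-only or vial-only), a training-set batch count, a training
#' window in months, and a replicate count.
#'
#' @param setting `"full"` (30 batches), `"syringe_only"` (17) or
#'   `"vial_only"` (13).
#' @param n_batches_train batches sampled into training (must not exceed
#'   the setting's total).
#' @param train_window_months training window, one of 4, 6, 9, 12.
#' @param n_replicates simulated replicates (default 50).
#' @param base_seed integer base seed.
#' @return object of class `scenario_spec`.
#' @export
scenario_spec <- function(setting = c("full", "syringe_only", "vial_only"),
                          n_batches_train, train_window_months,
                          n_replicates = 50L, base_seed = 1L) {
  setting <- match.arg(setting)
  totals <- c(full = 30L, syringe_only = 17L, vial_only = 13L)
  if (n_batches_train > totals[[setting]]) {
    stop("scenario error: n_batches_train (", n_batches_train,
         ") exceeds the ", setting, " setting total (", totals[[setting]],
         ")", call. = FALSE)
  }
  if (!(train_window_months %in% c(4, 6, 9, 12))) {
    stop("train_window_months must be one of 4, 6, 9, 12", call. = FALSE)
  }
  structure(list(setting = setting,
                 n_batches_train = as.integer(n_batches_train),
                 train_window_months = as.numeric(train_window_months),
                 n_replicates = as.integer(n_replicates),
                 base_seed = as.integer(base_seed)),
            class = "scenario_spec")
}

#' Full benchmark scenario grid
#'
#' The complete study design: batch sizes 5, 10, 15, 20, 30 for the full
#' setting and 5, 10 for syringe-only and vial-only, each crossed with
#' training windows of 4, 6, 9 and 12 months.
#'
#' @param settings which settings to include.
#' @param n_replicates replicates per scenario.
#' @param base_seed integer base seed.
#' @return list of [scenario_spec()] objects.
#' @export
full_scenario_grid <- function(settings = c("full", "syringe_only",
                                            "vial_only"),
                               n_replicates = 50L, base_seed = 1L) {
  sizes <- list(full = c(5L, 10L, 15L, 20L, 30L),
                syringe_only = c(5L, 10L), vial_only = c(5L, 10L))
  out <- list()
  for (s in settings) {
    for (nb in sizes[[s]]) {
      for (w in c(4, 6, 9, 12)) {
        out[[length(out) + 1L]] <- scenario_spec(s, nb, w, n_replicates,
                                                 base_seed)
      }
    }
  }
  out
}

setting_design <- function(setting, design) {
  switch(setting,
         full = design,
         syringe_only = cohort_design(
           n_batches = 17L, container_split = c(syringe = 17L),
           type_labels = design$type_labels,
           temperature_set = design$temperature_set,
           full_grid = design$full_grid,
           training_grid = design$training_grid),
         vial_only = cohort_design(
           n_batches = 13L, container_split = c(vial = 13L),
           type_labels = design$type_labels,
           temperature_set = design$temperature_set,
           full_grid = design$full_grid,
           training_grid = design$training_grid))
}

#' Run the coverage/MSE simulation study
#'
#' For each scenario and replicate: simulate a cohort from known truth,
#' sample `n_batches_train` batches without replacement, truncate their
#' records to the training window (all temperatures), fit the requested
#' models, predict each sampled batch's 5 degree observations beyond the
#' window, and record empirical coverage of the 95%-nominal intervals and
#' MSE overall and by molecular type. Deterministic given the scenario
#' `base_seed` (truth, measurement noise and batch subsampling use separate
#' seed offsets so scenarios share cohorts).
#'
#' @param scenarios list of [scenario_spec()] objects.
#' @param config a [generator_config()].
#' @param design a [cohort_design()] (the full setting's design; container
#'   subsets are derived from it).
#' @param models subset of `c("hierarchical", "linear", "mixed")`.
#' @param alpha nominal miscoverage of the evaluated intervals.
#' @param holdout_temperature hold-out temperature (default 5).
#' @param priors,mcmc hierarchical-model settings.
#' @return list of class `simulation_result`: `results` (one row per
#'   scenario x replicate x model) and `mse_by_type` (long table).
#' @export
run_simulation_study <- function(scenarios, config = generator_config(),
                                 design = default_cohort_design(),
                                 models = c("hierarchical", "linear",
                                            "mixed"),
                                 alpha = 0.05, holdout_temperature = 5,
                                 priors = prior_config(),
                                 mcmc = mcmc_config()) {
  if (inherits(scenarios, "scenario_spec")) scenarios <- list(scenarios)
  rows <- list(); type_rows <- list()
  for (sc in scenarios) {
    des <- setting_design(sc$setting, design)
    for (rep_i in seq_len(sc$n_replicates)) {
      seed_truth <- sc$base_seed + rep_i
      seed_data <- sc$base_seed + 100000L + rep_i
      seed_pick <- sc$base_seed + 200000L + rep_i
      params <- sample_true_parameters(config, des, seed = seed_truth)
      ds <- simulate_dataset(params, des, seed = seed_data)
      rng <- local_rng(seed_pick)
      picked <- sort(sample(unique(ds$batch_id), sc$n_batches_train))
      restore_rng(rng)
      sub <- ds[ds$batch_id %in% picked, , drop = FALSE]
      train <- sub[sub$time_months <= sc$train_window_months, , drop = FALSE]
      test <- sub[sub$time_months > sc$train_window_months &
                    sub$temperature_C == holdout_temperature, , drop = FALSE]
      class(train) <- class(test) <- c("stability_dataset", "data.frame")
      for (at in c("type_labels", "temperature_set", "spec_limit")) {
        attr(train, at) <- attr(test, at) <- attr(ds, at)
      }
      for (model in models) {
        fp <- fit_and_predict(model, train, test, alpha, priors, mcmc,
                              pred_seed = seed_data + 300000L)
        cr <- empirical_coverage(fp$intervals[[1L]], fp$test, model)
        m <- prediction_mse_by_type(fp$intervals[[1L]], fp$test)
        rows[[length(rows) + 1L]] <- data.frame(
          setting = sc$setting, n_batches_train = sc$n_batches_train,
          train_window_months = sc$train_window_months, replicate = rep_i,
          model = model, n_points = cr$n_points,
          coverage = cr$empirical_coverage, mse = m$overall,
          seed = seed_data, batches = paste(picked, collapse = "|"))
        type_rows[[length(type_rows) + 1L]] <- data.frame(
          setting = sc$setting, n_batches_train = sc$n_batches_train,
          train_window_months = sc$train_window_months, replicate = rep_i,
          model = model, molecular_type = names(m$by_type),
          mse = unname(m$by_type))
      }
    }
  }
  structure(list(results = do.call(rbind, rows) |> `rownames<-`(NULL),
                 mse_by_type = do.call(rbind, type_rows) |>
                   `rownames<-`(NULL)),
            class = "simulation_result")
}

#' Prediction-interval width versus training-data quantity
#'
#' Estimates how much data is needed for a target prediction width: for
#' each candidate number of training batches, simulates replicate cohorts,
#' fits the hierarchical model, and averages the predictive interval width
#' at the target coordinates.
#'
#' @param config a [generator_config()].
#' @param design a [cohort_design()].
#' @param data_sizes increasing numbers of training batches.
#' @param target single target (named list) as in [predictive_interval()].
#' @param alpha miscoverage level of the measured interval.
#' @param n_replicates replicates per size.
#' @param base_seed integer seed.
#' @param width_threshold optional target width.
#' @param priors,mcmc hierarchical-model settings.
#' @return list: `table` (size, mean_width), `smallest_size` meeting the
#'   threshold (`NA` = not reached, `NULL` when no threshold given).
#' @export
interval_width_curve <- function(config = generator_config(),
                                 design = default_cohort_design(),
                                 data_sizes = c(5L, 10L, 20L, 30L),
                                 target = list(batch_id = "new-batch",
                                               molecular_type = "A",
                                               container = "vial",
                                               temperature_C = 5,
                                               time_months = 36),
                                 alpha = 0.05, n_replicates = 3L,
                                 base_seed = 1L, width_threshold = NULL,
                                 priors = prior_config(),
                                 mcmc = mcmc_config()) {
  stopifnot(!is.unsorted(data_sizes))
  widths <- sapply(data_sizes, function(size) {
    mean(sapply(seq_len(n_replicates), function(rep_i) {
      params <- sample_true_parameters(config, design,
                                       seed = base_seed + rep_i)
      ds <- simulate_dataset(params, design,
                             seed = base_seed + 100000L + rep_i,
                             use_training_grid = TRUE)
      rng <- local_rng(base_seed + 200000L + rep_i)
      picked <- sample(unique(ds$batch_id), size)
      restore_rng(rng)
      sub <- ds[ds$batch_id %in% picked, , drop = FALSE]
      class(sub) <- c("stability_dataset", "data.frame")
      attr(sub, "type_labels") <- attr(ds, "type_labels")
      attr(sub, "temperature_set") <- attr(ds, "temperature_set")
      draws <- fit_gibbs(sub, priors = priors, mcmc = mcmc)
      iv <- predictive_interval(draws, target, alpha = alpha,
                                seed = base_seed + 300000L + rep_i)
      iv$upper - iv$lower
    }))
  })
  tab <- data.frame(n_batches = data_sizes, mean_width = widths)
  smallest <- NULL
  if (!is.null(width_threshold)) {
    hit <- which(widths <= width_threshold)
    smallest <- if (length(hit) > 0L) data_sizes[min(hit)] else NA_integer_
  }
  list(table = tab, smallest_size = smallest,
       width_threshold = width_threshold)
}

#' Prior-sensitivity scan
#'
#' Refits the model under each prior configuration (shared seed) and
#' tabulates a scalar quantity of interest, by default the one-sided lower
#' 95% bound of a new vial batch's mean profile at 36 months and 5 C for
#' the first molecular type.
#'
#' @param ds a [stability_dataset()].
#' @param prior_grid list of [prior_config()] objects.
#' @param quantity function `(posterior_draws) -> number`.
#' @param mcmc an [mcmc_config()] (seed shared across grid cells).
#' @return data.frame, one row per prior configuration, with the prior
#'   settings, the quantity (`NA` on fit failure, message in `error`), and
#'   attribute `"range"` (max - min over successful cells).
#' @export
prior_sensitivity_scan <- function(ds, prior_grid,
                                   quantity = NULL,
                                   mcmc = mcmc_config()) {
  if (inherits(prior_grid, "prior_config")) prior_grid <- list(prior_grid)
  stopifnot(length(prior_grid) >= 1L)
  if (is.null(quantity)) {
    quantity <- function(draws) {
      sl <- estimate_shelf_life(draws, molecular_type = draws$types[1L],
                                container = "vial", spec_limit = 0,
                                horizon = 36, grid_step = 36)
      unname(attr(sl, "bound")["36"])
    }
  }
  rows <- lapply(seq_along(prior_grid), function(i) {
    pr <- prior_grid[[i]]
    res <- tryCatch(
      list(value = quantity(fit_gibbs(ds, priors = pr, mcmc = mcmc)),
           error = NA_character_),
      error = function(e) list(value = NA_real_,
                               error = conditionMessage(e)))
    data.frame(prior = i,
               mean_prior_variance = pr$mean_prior_variance,
               variance_prior_shape = pr$variance_prior_shape,
               variance_prior_rate = pr$variance_prior_rate,
               interval_inflation = pr$interval_inflation,
               value = res$value, error = res$error)
  })
  out <- do.call(rbind, rows)
  vals <- out$value[is.finite(out$value)]
  attr(out, "range") <- if (length(vals) > 0L) diff(range(vals)) else NA_real_
  out
}
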