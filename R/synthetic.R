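# Synthetic multivalent-vaccine stability cohorts.
#
# The generator mirrors the hierarchy fitted by fit_gibbs(): batch-level
# intercepts and slopes scattered around type-level means, which scatter
# around global means, an additive container offset, and iid normal assay
# noise that dominates the observed variability.

#' Default cohort design
#'
#' The default study design: 30 batches (17 pre-filled syringe, 13 vial),
#' 9 molecular types per batch, storage at 5 / 25 / 37 degrees C. The full
#' grid carries long-term 5 degree data to 36 months plus short accelerated
#' series; the training grid holds 8 (temperature, time) points per
#' batch-and-type, so the default training design has
#' 30 x 9 x 8 = 2160 records.
#'
#' @param n_batches total number of batches.
#' @param container_split named counts per container, summing to `n_batches`.
#' @param type_labels ordered molecular-type labels.
#' @param temperature_set storage temperatures in degrees C.
#' @param full_grid named list mapping temperature to time points (months).
#' @param training_grid named list mapping temperature to the reduced
#'   training time points.
#' @return object of class `cohort_design`.
#' @export
cohort_design <- function(n_batches = 30L,
                          container_split = c(syringe = 17L, vial = 13L),
                          type_labels = LETTERS[1:9],
                          temperature_set = c(5, 25, 37),
                          full_grid = list(`5`  = c(0, 3, 6, 9, 12, 18, 24, 30, 36),
                                           `25` = c(0, 1, 2, 3, 6),
                                           `37` = c(0, 1, 2, 3)),
                          training_grid = list(`5`  = c(0, 3, 6),
                                               `25` = c(1, 3, 6),
                                               `37` = c(1, 3))) {
  stopifnot(n_batches >= 1L, length(type_labels) >= 1L)
  if (sum(container_split) != n_batches) {
    stop("container_split must sum to n_batches", call. = FALSE)
  }
  if (!all(names(container_split) %in% CONTAINER_LEVELS)) {
    stop("container_split names must be in {",
         paste(CONTAINER_LEVELS, collapse = ", "), "}", call. = FALSE)
  }
  if (!setequal(names(full_grid), as.character(temperature_set)) ||
      !setequal(names(training_grid), as.character(temperature_set))) {
    stop("full_grid and training_grid must name every temperature",
         call. = FALSE)
  }
  for (tp in names(training_grid)) {
    extra <- setdiff(training_grid[[tp]], full_grid[[tp]])
    if (any(extra > max(full_grid[[tp]]))) {
      stop("training_grid points beyond the full grid's horizon are not ",
           "allowed (temperature ", tp, ")", call. = FALSE)
    }
  }
  structure(list(n_batches = as.integer(n_batches),
                 container_split = container_split,
                 type_labels = as.character(type_labels),
                 temperature_set = as.numeric(temperature_set),
                 full_grid = lapply(full_grid, as.numeric),
                 training_grid = lapply(training_grid, as.numeric)),
            class = "cohort_design")
}

#' @rdname cohort_design
#' @export
default_cohort_design <- function() cohort_design()

#' Number of records a design generates
#'
#' @param design a `cohort_design`.
#' @param use_training_grid count the training grid instead of the full grid.
#' @return integer record count (batches x types x grid points).
#' @export
design_record_count <- function(design, use_training_grid = FALSE) {
  grid <- if (use_training_grid) design$training_grid else design$full_grid
  design$n_batches * length(design$type_labels) *
    sum(lengths(grid))
}

#' Generator settings for the true hierarchy
#'
#' Hyper-settings from which [sample_true_parameters()] realizes a truth.
#' Defaults emulate the qualitative phenomenology of a refrigerated
#' multivalent vaccine potency study: intercept near 100% of label claim,
#' small loss at 5 C and pronounced loss at 37 C, between-type and
#' between-batch spread small relative to assay noise (so that >= 80% of
#' observed variability is batch- and type-independent noise), and an
#' optional saturating-exponential taper of the time trend.
#'
#' @param grand_intercept mean potency at time 0 (percent of label claim).
#' @param type_intercept_sd between-type intercept SD (percent), tau_a.
#' @param batch_intercept_sd between-batch intercept SD (percent), sigma_a.
#' @param container_offset named additive offsets (percent); vial is the
#'   reference at 0.
#' @param slope_mean_by_temp named global mean degradation slopes
#'   (percent/month), non-positive and non-increasing in temperature.
#' @param type_slope_sd between-type slope SD around the global mean
#'   (percent/month), tau_b.
#' @param batch_slope_sd between-batch slope SD around the type mean
#'   (percent/month), sigma_b.
#' @param residual_sd assay noise SD (percent), sigma.
#' @param taper_rate kappa >= 0 per month; 0 gives an exactly linear trend,
#'   kappa > 0 replaces t by (1 - exp(-kappa t)) / kappa.
#' @return list of class `generator_config`.
#' @export
generator_config <- function(grand_intercept = 100,
                             type_intercept_sd = 0.5,
                             batch_intercept_sd = 1.0,
                             container_offset = c(vial = 0, syringe = 0.5),
                             slope_mean_by_temp = c(`5` = -0.05, `25` = -0.8,
                                                    `37` = -2.5),
                             type_slope_sd = 0.05,
                             batch_slope_sd = 0.02,
                             residual_sd = 4.0,
                             taper_rate = 0) {
  sds <- c(type_intercept_sd, batch_intercept_sd, type_slope_sd,
           batch_slope_sd, residual_sd)
  if (any(!is.finite(sds)) || any(sds < 0)) {
    stop("all standard deviations must be finite and >= 0", call. = FALSE)
  }
  if (taper_rate < 0) stop("taper_rate must be >= 0", call. = FALSE)
  sl <- slope_mean_by_temp[order(as.numeric(names(slope_mean_by_temp)))]
  if (any(sl > 0) || is.unsorted(rev(sl))) {
    stop("slope_mean_by_temp must be <= 0 and non-increasing with ",
         "temperature (degradation accelerates when warmer)", call. = FALSE)
  }
  structure(list(grand_intercept = grand_intercept,
                 type_intercept_sd = type_intercept_sd,
                 batch_intercept_sd = batch_intercept_sd,
                 container_offset = container_offset,
                 slope_mean_by_temp = sl,
                 type_slope_sd = type_slope_sd,
                 batch_slope_sd = batch_slope_sd,
                 residual_sd = residual_sd,
                 taper_rate = taper_rate),
            class = "generator_config")
}

#' Arrhenius-parameterized global slope means
#'
#' Alternative to listing per-temperature slope means: a single activation
#' energy ties degradation rates across temperatures,
#' `M_T = -A * exp(-Ea / (R * T_K))` with `T_K = T_C + 273.15` and
#' R = 8.31446e-3 kJ/(mol K).
#'
#' @param pre_exponential A, in percent/month (positive).
#' @param activation_energy_kJ Ea in kJ/mol.
#' @param temperatures_C temperatures at which to evaluate.
#' @return named vector of non-positive slope means (percent/month).
#' @export
arrhenius_slope_means <- function(pre_exponential, activation_energy_kJ,
                                  temperatures_C = c(5, 25, 37)) {
  stopifnot(pre_exponential > 0, activation_energy_kJ >= 0)
  R <- 8.31446e-3
  TK <- temperatures_C + 273.15
  out <- -pre_exponential * exp(-activation_energy_kJ / (R * TK))
  names(out) <- as.character(temperatures_C)
  out
}

#' Realize true hierarchy parameters
#'
#' Draws the type-level layers of the hierarchy (type intercept offsets
#' around 0 with SD tau_a; type slope means around the global
#' per-temperature means with SD tau_b) and records every realized value,
#' so simulated datasets have a fully known truth.
#'
#' @param config a [generator_config()].
#' @param design a [cohort_design()] (supplies type labels and temperatures).
#' @param seed integer seed; identical seeds give identical parameters.
#' @return object of class `true_parameters`.
#' @export
sample_true_parameters <- function(config = generator_config(),
                                   design = default_cohort_design(),
                                   seed = 1L) {
  stopifnot(inherits(config, "generator_config"),
            inherits(design, "cohort_design"))
  missing_T <- setdiff(as.character(design$temperature_set),
                       names(config$slope_mean_by_temp))
  if (length(missing_T) > 0L) {
    stop("slope_mean_by_temp lacks temperature(s): ",
         paste(missing_T, collapse = ", "), call. = FALSE)
  }
  n_types <- length(design$type_labels)
  temps <- as.character(design$temperature_set)
  rng <- local_rng(seed)
  type_intercepts <- stats::rnorm(n_types, 0, config$type_intercept_sd)
  names(type_intercepts) <- design$type_labels
  type_slope_means <- matrix(0, n_types, length(temps),
                             dimnames = list(design$type_labels, temps))
  for (tp in temps) {
    type_slope_means[, tp] <- config$slope_mean_by_temp[[tp]] +
      stats::rnorm(n_types, 0, config$type_slope_sd)
  }
  restore_rng(rng)
  structure(list(grand_intercept = config$grand_intercept,
                 type_intercepts = type_intercepts,
                 batch_intercept_sd = config$batch_intercept_sd,
                 container_offset = config$container_offset,
                 slope_mean_by_temp = config$slope_mean_by_temp[temps],
                 type_slope_means = type_slope_means,
                 type_slope_sd = config$type_slope_sd,
                 batch_slope_sd = config$batch_slope_sd,
                 residual_sd = config$residual_sd,
                 taper_rate = config$taper_rate),
            class = "true_parameters")
}

# Saturating time transform of the generator: g(t) = t for kappa = 0,
# (1 - exp(-kappa t)) / kappa otherwise; g(t) < t for kappa > 0 so a taper
# always reduces total loss relative to the linear trend.
taper_transform <- function(t, kappa) {
  if (kappa == 0) t else (1 - exp(-kappa * t)) / kappa
}

#' Simulate a stability dataset from known truth
#'
#' For each (batch, type) an intercept is drawn around the type intercept;
#' for each (batch, type, temperature) a slope is drawn around the type
#' slope mean. Potency is
#' `intercept + container_offset + slope * g(time) + noise` with
#' `g` the taper transform and iid N(0, sigma^2) assay noise independent of
#' batch and type. Deterministic given `seed`.
#'
#' @param params a `true_parameters` object (see [sample_true_parameters()]).
#' @param design a [cohort_design()].
#' @param seed integer seed.
#' @param use_training_grid simulate the reduced training grid instead of
#'   the full grid.
#' @param spec_limit optional lower specification limit stored on the
#'   result.
#' @return a [stability_dataset()]; attribute `"true_means"` holds the
#'   noise-free mean of every record.
#' @export
simulate_dataset <- function(params, design = default_cohort_design(),
                             seed = 1L, use_training_grid = FALSE,
                             spec_limit = NULL) {
  stopifnot(inherits(params, "true_parameters"),
            inherits(design, "cohort_design"))
  grid <- if (use_training_grid) design$training_grid else design$full_grid
  containers <- rep(names(design$container_split), design$container_split)
  batch_ids <- sprintf("B%02d", seq_len(design$n_batches))
  types <- design$type_labels
  temps <- as.character(design$temperature_set)

  grid_df <- do.call(rbind, lapply(temps, function(tp) {
    data.frame(temperature_C = as.numeric(tp), time_months = grid[[tp]])
  }))
  frame <- expand.grid(grid_idx = seq_len(nrow(grid_df)),
                       molecular_type = types, batch = seq_along(batch_ids),
                       KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  rec <- data.frame(batch_id = batch_ids[frame$batch],
                    molecular_type = frame$molecular_type,
                    container = containers[frame$batch],
                    temperature_C = grid_df$temperature_C[frame$grid_idx],
                    time_months = grid_df$time_months[frame$grid_idx],
                    stringsAsFactors = FALSE)

  rng <- local_rng(seed)
  n_bt <- design$n_batches * length(types)
  bt <- expand.grid(molecular_type = types, batch = seq_along(batch_ids),
                    KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  bt_key <- paste(batch_ids[bt$batch], bt$molecular_type, sep = "\r")
  bt_intercept <- params$grand_intercept +
    params$type_intercepts[bt$molecular_type] +
    stats::rnorm(n_bt, 0, params$batch_intercept_sd)
  names(bt_intercept) <- bt_key
  # slopes per (batch, type, temperature)
  btT <- merge(bt, data.frame(temperature_C = as.numeric(temps)))
  btT_key <- paste(batch_ids[btT$batch], btT$molecular_type,
                   btT$temperature_C, sep = "\r")
  btT_slope <- params$type_slope_means[cbind(btT$molecular_type,
                                             as.character(btT$temperature_C))] +
    stats::rnorm(nrow(btT), 0, params$batch_slope_sd)
  names(btT_slope) <- btT_key

  rec_bt <- paste(rec$batch_id, rec$molecular_type, sep = "\r")
  rec_btT <- paste(rec$batch_id, rec$molecular_type, rec$temperature_C,
                   sep = "\r")
  mean_pot <- bt_intercept[rec_bt] +
    params$container_offset[rec$container] +
    btT_slope[rec_btT] * taper_transform(rec$time_months, params$taper_rate)
  rec$potency <- mean_pot + stats::rnorm(nrow(rec), 0, params$residual_sd)
  restore_rng(rng)

  ds <- stability_dataset(rec, type_labels = types,
                          temperature_set = design$temperature_set,
                          spec_limit = spec_limit)
  attr(ds, "true_means") <- unname(mean_pot)
  attr(ds, "true_parameters") <- params
  ds
}

#' Residual (assay-noise) variance fraction
#'
#' Decomposes the variability of a cohort about its pooled ("grand")
#' degradation structure into the part explained by batch/type-specific
#' mean structure and a residual assay-noise part. Returns the noise share
#' `MS_resid / MS_total`, both mean squares degrees-of-freedom corrected so
#' that a saturated mean structure does not deflate the estimate. Also
#' reports per-batch residual variances and their max/min ratio as a check
#' that assay noise is batch-independent.
#'
#' @param ds a `stability_dataset` with at least 2 records.
#' @param fit the batch/type-specific mean structure: `NULL` (default) fits
#'   per-(batch, type) ordinary least squares with temperature-specific
#'   slopes internally; a numeric vector is taken as known mean predictions
#'   (0 model degrees of freedom); a [fit_perbatch_linear()] object uses its
#'   fitted values and parameter count.
#' @return list of class `variance_decomposition` with elements `fraction`
#'   (noise share in [0, 1]), `per_batch_variance`, `homogeneity_ratio`,
#'   and the two mean squares.
#' @export
residual_variance_fraction <- function(ds, fit = NULL) {
  rec <- as.data.frame(ds)
  n <- nrow(rec)
  if (n < 2L) stop("undefined for fewer than 2 records", call. = FALSE)

  # pooled grand structure: common temperature-specific slopes + container
  g <- taper_free_design(rec)
  grand <- stats::lm.fit(g, rec$potency)
  ss_total <- sum(grand$residuals^2)
  df_total <- n - grand$rank

  if (is.null(fit)) fit <- fit_perbatch_linear(ds)
  if (inherits(fit, "perbatch_linear_fit")) {
    fitted_vals <- fitted_values(fit, rec)
    df_model <- fit$n_parameters
  } else if (is.numeric(fit)) {
    stopifnot(length(fit) == n)
    fitted_vals <- fit
    df_model <- 0L
  } else {
    stop("fit must be NULL, a numeric vector, or a perbatch_linear_fit",
         call. = FALSE)
  }
  resid <- rec$potency - fitted_vals
  df_resid <- max(n - df_model, 1L)
  ms_resid <- sum(resid^2) / df_resid
  ms_total <- ss_total / max(df_total, 1L)
  fraction <- if (ms_total == 0) 0 else min(ms_resid / ms_total, 1)

  per_batch <- tapply(seq_len(n), rec$batch_id, function(idx) {
    nb <- length(idx)
    dfb <- max(nb - df_model * nb / n, 1)
    sum(resid[idx]^2) / dfb
  })
  per_batch <- unlist(per_batch)
  ratio <- if (all(per_batch > 0)) max(per_batch) / min(per_batch) else NA_real_
  structure(list(fraction = fraction,
                 ms_resid = ms_resid, ms_total = ms_total,
                 per_batch_variance = per_batch,
                 homogeneity_ratio = ratio),
            class = "variance_decomposition")
}

# pooled design: intercept, container offset, slope per temperature
taper_free_design <- function(rec) {
  temps <- sort(unique(rec$temperature_C))
  X <- cbind(`(Intercept)` = rep(1, nrow(rec)))
  if (length(unique(rec$container)) > 1L) {
    X <- cbind(X, syringe = as.numeric(rec$container == "syringe"))
  }
  for (tp in temps) {
    X <- cbind(X, rec$time_months * (rec$temperature_C == tp))
    colnames(X)[ncol(X)] <- paste0("slope_", tp)
  }
  X
}

# Seed hygiene: draw under a local RNG state, then restore the caller's.
local_rng <- function(seed) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv())
  } else NULL
  set.seed(as.integer(seed))
  old
}

restore_rng <- function(old) {
  if (is.null(old)) {
    rm(".Random.seed", envir = globalenv())
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
  invisible(NULL)
}
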