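# Posterior prediction: mean-profile and posterior predictive intervals,
# shelf-life estimation, posterior summaries, draw persistence.

NEW_BATCH <- "new-batch"

#' Packaged default lower specification limit
#'
#' Normalized-potency lower specification limit used by default in
#' shelf-life estimation: 85 percent of label claim, a typical stability
#' acceptance limit for a potency attribute with high assay variability.
#'
#' @return a single number (percent of label claim).
#' @export
default_spec_limit <- function() 85

# draws of the stability profile (no assay noise) at each newdata row:
# n_draws x nrow(newdata) matrix. With batch_effects = TRUE, new-batch rows
# get fresh batch-level intercepts/slopes from the hierarchy, drawn once
# per (type, temperature) and shared across rows so a new batch has one
# coherent profile per posterior draw; with batch_effects = FALSE they use
# the type-level mean trend (a_t + gamma + m[t,T] * time). Seen batches use
# their own posterior effects either way.
profile_draws <- function(draws, newdata, batch_effects = TRUE) {
  n_draws <- length(draws$mu_alpha)
  nd <- nrow(newdata)
  sig_a <- sqrt(draws$variances[, "sigma_a2"])
  sig_b <- sqrt(draws$variances[, "sigma_b2"])
  tau_b <- sqrt(draws$variances[, "tau_b2"])
  arrhenius <- !is.null(draws$arrhenius)
  Rgas <- 8.31446e-3
  new_alpha <- new.env(parent = emptyenv())
  new_slope <- new.env(parent = emptyenv())
  out <- matrix(0, n_draws, nd)

  for (j in seq_len(nd)) {
    ty <- newdata$molecular_type[j]
    tp <- as.character(newdata$temperature_C[j])
    b <- newdata$batch_id[j]
    cont <- newdata$container[j]
    if (!(ty %in% draws$types)) {
      stop("molecular type not in training data: ", ty, call. = FALSE)
    }
    seen_temp <- tp %in% colnames(draws$M_T)
    if (!seen_temp && !arrhenius) {
      stop("extrapolation error: temperature ", tp, " C not in training ",
           "data; refit with model_spec(slope_model = 'arrhenius')",
           call. = FALSE)
    }
    gamma <- if (identical(cont, "syringe")) draws$gamma_syringe else 0

    if (identical(b, NEW_BATCH)) {
      akey <- ty
      if (is.null(new_alpha[[akey]])) {
        new_alpha[[akey]] <- if (batch_effects) {
          draws$a_type[, ty] + stats::rnorm(n_draws, 0, sig_a)
        } else {
          draws$a_type[, ty]
        }
      }
      alpha_d <- new_alpha[[akey]]
      skey <- paste(ty, tp, sep = "\r")
      if (is.null(new_slope[[skey]])) {
        m_d <- if (seen_temp && skey %in% colnames(draws$m_tT)) {
          draws$m_tT[, skey]
        } else {
          M_d <- if (seen_temp) draws$M_T[, tp] else {
            TKs <- as.numeric(tp) + 273.15
            -exp(draws$arrhenius[, "log_A"] -
                   draws$arrhenius[, "Ea_kJ"] / (Rgas * TKs))
          }
          M_d + stats::rnorm(n_draws, 0, tau_b)
        }
        new_slope[[skey]] <- if (batch_effects) {
          m_d + stats::rnorm(n_draws, 0, sig_b)
        } else m_d
      }
      beta_d <- new_slope[[skey]]
    } else {
      bt_key <- paste(b, ty, sep = "\r")
      btT_key <- paste(b, ty, tp, sep = "\r")
      if (!(bt_key %in% draws$bt_levels) ||
          !(btT_key %in% draws$btT_levels)) {
        stop("stratum not seen in training: batch ", b, ", type ", ty,
             ", ", tp, " C (use batch_id = \"", NEW_BATCH,
             "\" for new batches)", call. = FALSE)
      }
      alpha_d <- draws$alpha_bt[, bt_key]
      beta_d <- draws$beta_btT[, btT_key]
    }
    out[, j] <- alpha_d + gamma + beta_d * newdata$time_months[j]
  }
  out
}

#' Prediction intervals at a set of target coordinates
#'
#' Central (1 - alpha) posterior intervals at each row of `newdata`.
#' `kind = "predictive"` simulates new observations: profile plus fresh
#' assay noise, with fresh batch-level effects drawn from the hierarchy
#' when `batch_id == "new-batch"`. `kind = "mean_profile"` summarizes the
#' mean trend only (for a new batch: the type-level trend
#' `a_t + gamma_c + m[t,T] * time`, without batch-level scatter). The
#' configured `interval_inflation` scales the spread about the interval
#' center.
#'
#' @param draws a [fit_gibbs()] result.
#' @param newdata data.frame with columns `batch_id` (a training batch id
#'   or `"new-batch"`), `molecular_type`, `container`, `temperature_C`,
#'   `time_months`.
#' @param alpha miscoverage level in (0, 1); 0.05 gives 95% intervals.
#' @param kind `"predictive"` or `"mean_profile"`.
#' @param seed optional seed for the predictive simulation.
#' @return data.frame of class `prediction_interval`: the target
#'   coordinates plus `alpha`, `kind`, `lower`, `center`, `upper`.
#' @export
predict_intervals <- function(draws, newdata, alpha = 0.05,
                              kind = c("predictive", "mean_profile"),
                              seed = NULL) {
  kind <- match.arg(kind)
  stopifnot(alpha > 0, alpha < 1)
  newdata <- as.data.frame(newdata)
  rng <- if (!is.null(seed)) local_rng(seed)
  prof <- profile_draws(draws, newdata,
                        batch_effects = kind == "predictive")
  center <- colMeans(prof)
  if (kind == "predictive") {
    sigma <- sqrt(draws$variances[, "sigma2"])
    prof <- prof + matrix(stats::rnorm(length(prof), 0, sigma),
                          nrow(prof), ncol(prof))
  }
  if (!is.null(seed)) restore_rng(rng)
  q <- apply(prof, 2L, stats::quantile,
             probs = c(alpha / 2, 1 - alpha / 2), names = FALSE)
  infl <- draws$priors$interval_inflation
  out <- newdata[c("batch_id", "molecular_type", "container",
                   "temperature_C", "time_months")]
  out$alpha <- alpha
  out$kind <- kind
  out$lower <- center + infl * (q[1L, ] - center)
  out$center <- center
  out$upper <- center + infl * (q[2L, ] - center)
  class(out) <- c("prediction_interval", "data.frame")
  out
}

#' @rdname predict_intervals
#' @param target a single target as a named list (fields as `newdata`).
#' @export
predictive_interval <- function(draws, target, alpha = 0.05,
                                kind = c("predictive", "mean_profile"),
                                seed = NULL) {
  predict_intervals(draws, as.data.frame(target, stringsAsFactors = FALSE),
                    alpha = alpha, kind = kind, seed = seed)
}

#' Shelf-life estimate from the fitted model
#'
#' Shelf life is operationalized as the largest time on a monthly grid at
#' which the one-sided lower `level` bound of the stability profile of a
#' new batch, at the long-term storage temperature, stays at or above the
#' lower specification limit for all earlier grid times. Returns `horizon`
#' when the bound never crosses the limit and 0 when it is already below
#' at time 0. Grid ties resolve downward (conservative).
#'
#' @param draws a [fit_gibbs()] result.
#' @param molecular_type type label (must be in training data).
#' @param container `"vial"` or `"syringe"`.
#' @param spec_limit lower specification limit (percent of label claim).
#' @param temperature storage temperature in degrees C (default 5).
#' @param horizon maximum month considered (default 48).
#' @param level one-sided confidence level of the lower bound
#'   (default 0.95, i.e. the 5th posterior percentile).
#' @param grid_step grid resolution in months.
#' @param kind `"mean_profile"` (default: bound on the mean trend) or
#'   `"predictive"` (bound on new single observations).
#' @param seed optional seed for the predictive simulation.
#' @return shelf life in months (a grid value, 0, or `horizon`), with the
#'   per-month bound attached as attribute `"bound"`.
#' @export
estimate_shelf_life <- function(draws, molecular_type, container = "vial",
                                spec_limit = default_spec_limit(),
                                temperature = 5, horizon = 48, level = 0.95,
                                grid_step = 1,
                                kind = c("mean_profile", "predictive"),
                                seed = NULL) {
  kind <- match.arg(kind)
  if (length(draws$mu_alpha) == 0L) stop("empty draws", call. = FALSE)
  grid <- seq(0, horizon, by = grid_step)
  newdata <- data.frame(batch_id = NEW_BATCH,
                        molecular_type = molecular_type,
                        container = container,
                        temperature_C = temperature,
                        time_months = grid,
                        stringsAsFactors = FALSE)
  # one-sided bound: center + inflation * (q_{1-level} - center)
  iv <- predict_intervals(draws, newdata, alpha = 2 * (1 - level),
                          kind = kind, seed = seed)
  bound <- iv$lower
  ok <- bound >= spec_limit
  shelf <- if (all(ok)) {
    max(grid)
  } else if (!ok[1L]) {
    0
  } else {
    grid[which(!ok)[1L] - 1L]
  }
  structure(shelf, bound = stats::setNames(bound, grid))
}

# all scalar parameters as one draws matrix with readable names
param_matrix <- function(draws) {
  fix <- function(m, base) {
    # ":" separates index levels (comma would break the CSV audit format)
    colnames(m) <- sprintf("%s[%s]", base,
                           gsub("\r", ":", colnames(m), fixed = TRUE))
    m
  }
  parts <- list(mu_alpha = cbind(mu_alpha = draws$mu_alpha))
  if (draws$two_containers) {
    parts$gamma <- cbind(gamma_syringe = draws$gamma_syringe)
  }
  parts$a <- fix(draws$a_type, "a")
  parts$alpha <- fix(draws$alpha_bt, "alpha")
  parts$M <- fix(draws$M_T, "M")
  parts$m <- fix(draws$m_tT, "m")
  parts$beta <- fix(draws$beta_btT, "beta")
  parts$variances <- draws$variances
  if (!is.null(draws$arrhenius)) parts$arrh <- draws$arrhenius
  do.call(cbind, unname(parts))
}

#' Posterior summary table
#'
#' One row per scalar parameter: posterior mean, SD, and a central credible
#' interval.
#'
#' @param draws a [fit_gibbs()] result.
#' @param credible_level central credible mass (default 0.95).
#' @return data.frame with columns `parameter`, `mean`, `sd`, `lower`,
#'   `upper`.
#' @export
posterior_summary <- function(draws, credible_level = 0.95) {
  stopifnot(credible_level > 0, credible_level < 1)
  if (length(draws$mu_alpha) == 0L) stop("empty draws", call. = FALSE)
  pm <- param_matrix(draws)
  p <- (1 - credible_level) / 2
  q <- apply(pm, 2L, stats::quantile, probs = c(p, 1 - p), names = FALSE)
  data.frame(parameter = colnames(pm),
             mean = colMeans(pm),
             sd = apply(pm, 2L, stats::sd),
             lower = q[1L, ], upper = q[2L, ],
             row.names = NULL)
}

#' Persist posterior draws as a columnar text file
#'
#' Long CSV, one row per draw x parameter, for audit trails.
#'
#' @param draws a [fit_gibbs()] result.
#' @param path output CSV path.
#' @param parameters optional character vector restricting which parameters
#'   are written (default: all).
#' @return `path`, invisibly.
#' @export
write_posterior_draws <- function(draws, path, parameters = NULL) {
  pm <- param_matrix(draws)
  if (!is.null(parameters)) {
    keep <- colnames(pm) %in% parameters
    if (!any(keep)) stop("no matching parameters", call. = FALSE)
    pm <- pm[, keep, drop = FALSE]
  }
  long <- data.frame(chain = rep(draws$chain, ncol(pm)),
                     iteration = rep(draws$iteration, ncol(pm)),
                     parameter = rep(colnames(pm), each = nrow(pm)),
                     value = as.vector(pm))
  utils::write.csv(long, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
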