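# Baseline models for the simulation benchmark: per-batch ordinary least
# squares (no pooling across batches) and a single mixed-effects model
# (partial pooling through random batch effects). Both treat temperature as
# categorical with temperature-specific time slopes.

stratum_key <- function(batch_id, molecular_type) {
  paste(batch_id, molecular_type, sep = "\r")
}

# stratum design: common intercept + one time slope per temperature present
stratum_design <- function(time, temp, temps) {
  X <- cbind(`(Intercept)` = rep(1, length(time)))
  for (tp in temps) {
    X <- cbind(X, time * (temp == tp))
    colnames(X)[ncol(X)] <- paste0("slope_", tp)
  }
  X
}

#' Per-batch linear models
#'
#' Fits an ordinary least-squares line to each (batch, molecular type)
#' stratum separately: a common intercept and one slope per temperature
#' present in the stratum. No information is shared across batches or
#' types, so predictions for a batch are invariant to every other batch in
#' the training set. Strata with no more observations than parameters (or a
#' rank-deficient design) are marked unfittable and excluded from
#' prediction.
#'
#' @param ds a [stability_dataset()].
#' @return object of class `perbatch_linear_fit`.
#' @export
fit_perbatch_linear <- function(ds) {
  rec <- as.data.frame(ds)
  keys <- stratum_key(rec$batch_id, rec$molecular_type)
  strata <- list()
  unfittable <- character(0)
  total_rank <- 0L
  for (k in unique(keys)) {
    idx <- which(keys == k)
    temps <- sort(unique(rec$temperature_C[idx]))
    X <- stratum_design(rec$time_months[idx], rec$temperature_C[idx], temps)
    n_k <- length(idx)
    qrX <- qr(X)
    if (n_k <= ncol(X) || qrX$rank < ncol(X)) {
      unfittable <- c(unfittable, k)
      next
    }
    fit <- stats::lm.fit(X, rec$potency[idx])
    df <- n_k - ncol(X)
    strata[[k]] <- list(
      coefficients = fit$coefficients,
      temps = temps,
      xtx_inv = chol2inv(chol(crossprod(X))),
      sigma2 = sum(fit$residuals^2) / df,
      df = df, n = n_k)
    total_rank <- total_rank + ncol(X)
  }
  structure(list(strata = strata, unfittable = unfittable,
                 n_parameters = total_rank),
            class = "perbatch_linear_fit")
}

#' @export
print.perbatch_linear_fit <- function(x, ...) {
  cat(sprintf("<perbatch_linear_fit> %d fitted strata, %d unfittable\n",
              length(x$strata), length(x$unfittable)))
  invisible(x)
}

# fitted means at arbitrary records (internal; used by variance decomposition)
fitted_values <- function(fit, rec) {
  stopifnot(inherits(fit, "perbatch_linear_fit"))
  keys <- stratum_key(rec$batch_id, rec$molecular_type)
  out <- rep(NA_real_, nrow(rec))
  for (k in unique(keys)) {
    s <- fit$strata[[k]]
    if (is.null(s)) next
    idx <- which(keys == k)
    X <- stratum_design(rec$time_months[idx], rec$temperature_C[idx],
                        s$temps)
    out[idx] <- drop(X %*% s$coefficients)
  }
  out
}

#' Prediction intervals from per-batch linear fits
#'
#' Standard t-based prediction intervals for a new observation at each
#' target coordinate, using the stratum's own fit only.
#'
#' @param fits a [fit_perbatch_linear()] result.
#' @param newdata data.frame with `batch_id`, `molecular_type`,
#'   `temperature_C`, `time_months` (container is implicit in the batch).
#' @param alpha miscoverage level.
#' @return `prediction_interval` data.frame.
#' @export
predict_linear <- function(fits, newdata, alpha = 0.05) {
  stopifnot(alpha > 0, alpha < 1)
  newdata <- as.data.frame(newdata)
  nd <- nrow(newdata)
  lower <- center <- upper <- rep(NA_real_, nd)
  for (j in seq_len(nd)) {
    k <- stratum_key(newdata$batch_id[j], newdata$molecular_type[j])
    s <- fits$strata[[k]]
    if (is.null(s)) {
      stop("lookup error: stratum not fitted (batch ", newdata$batch_id[j],
           ", type ", newdata$molecular_type[j], ")", call. = FALSE)
    }
    tp <- newdata$temperature_C[j]
    if (!(tp %in% s$temps)) {
      stop("lookup error: temperature ", tp,
           " C not fitted in stratum ", gsub("\r", "/", k), call. = FALSE)
    }
    x <- c(1, newdata$time_months[j] * (s$temps == tp))
    pred <- sum(x * s$coefficients)
    se <- sqrt(s$sigma2 * (1 + drop(t(x) %*% s$xtx_inv %*% x)))
    tq <- stats::qt(1 - alpha / 2, df = s$df)
    center[j] <- pred
    lower[j] <- pred - tq * se
    upper[j] <- pred + tq * se
  }
  out <- newdata
  out$alpha <- alpha
  out$kind <- "predictive"
  out$lower <- lower; out$center <- center; out$upper <- upper
  class(out) <- c("prediction_interval", "data.frame")
  out
}

#' Mixed-effects comparator model
#'
#' One model for the whole training set, fitted by maximum likelihood with
#' lme4: fixed effects for time, temperature (categorical), their
#' interaction and container; independent random intercept and random time
#' slope per batch.
#'
#' @param ds a [stability_dataset()] with at least 2 batches.
#' @return object of class `mixed_fit`; element `singular` flags a
#'   degenerate (boundary) variance-component fit.
#' @export
fit_mixed_model <- function(ds) {
  rec <- as.data.frame(ds)
  if (length(unique(rec$batch_id)) < 2L) {
    stop("mixed model needs >= 2 batches", call. = FALSE)
  }
  rec$temperature_f <- factor(rec$temperature_C,
                              levels = sort(unique(rec$temperature_C)))
  two_containers <- length(unique(rec$container)) > 1L
  fixed <- if (two_containers) {
    potency ~ time_months * temperature_f + container
  } else {
    potency ~ time_months * temperature_f
  }
  form <- stats::update(fixed, . ~ . + (1 + time_months || batch_id))
  fit <- suppressMessages(suppressWarnings(
    lme4::lmer(form, data = rec, REML = FALSE)))
  vc <- as.data.frame(lme4::VarCorr(fit))
  var_int <- vc$vcov[vc$grp != "Residual" & vc$var1 == "(Intercept)"][1]
  var_slope <- vc$vcov[vc$grp != "Residual" & vc$var1 == "time_months"][1]
  sigma2 <- vc$vcov[vc$grp == "Residual"][1]
  structure(list(model = fit,
                 fixed_formula = fixed,
                 temp_levels = levels(rec$temperature_f),
                 two_containers = two_containers,
                 container_levels = sort(unique(rec$container)),
                 var_intercept = var_int, var_slope = var_slope,
                 sigma2 = sigma2,
                 singular = lme4::isSingular(fit),
                 batches = sort(unique(rec$batch_id))),
            class = "mixed_fit")
}

#' @export
print.mixed_fit <- function(x, ...) {
  cat(sprintf(
    "<mixed_fit> %d batches | batch var (int %.3g, slope %.3g) | sigma2 %.3g%s\n",
    length(x$batches), x$var_intercept, x$var_slope, x$sigma2,
    if (x$singular) " | SINGULAR" else ""))
  invisible(x)
}

#' Prediction intervals from the mixed-effects model
#'
#' Plug-in normal intervals: the point prediction adds the batch's
#' predicted (BLUP) random effects for a seen batch, or uses the population
#' level (adding the random-effect variances to the prediction variance)
#' for `batch_id == "new-batch"`. Variance = fixed-effect prediction
#' variance + (new-batch random-effect variance) + residual variance; no
#' degrees-of-freedom correction, so slight undercoverage at small samples
#' is expected and documented.
#'
#' @param fit a [fit_mixed_model()] result.
#' @param newdata data.frame with `batch_id`, `molecular_type`, `container`,
#'   `temperature_C`, `time_months`.
#' @param alpha miscoverage level.
#' @return `prediction_interval` data.frame.
#' @export
predict_mixed <- function(fit, newdata, alpha = 0.05) {
  stopifnot(alpha > 0, alpha < 1)
  newdata <- as.data.frame(newdata)
  bad_temp <- setdiff(unique(as.character(newdata$temperature_C)),
                      fit$temp_levels)
  if (length(bad_temp) > 0L) {
    stop("temperature(s) not in training data: ",
         paste(bad_temp, collapse = ", "), call. = FALSE)
  }
  new_flag <- newdata$batch_id == NEW_BATCH
  unseen <- setdiff(unique(newdata$batch_id[!new_flag]), fit$batches)
  if (length(unseen) > 0L) {
    stop("lookup error: batch(es) not in training data: ",
         paste(unseen, collapse = ", "),
         " (use batch_id = \"", NEW_BATCH, "\")", call. = FALSE)
  }
  nd2 <- newdata
  nd2$temperature_f <- factor(as.character(nd2$temperature_C),
                              levels = fit$temp_levels)
  if (fit$two_containers) {
    nd2$container <- factor(nd2$container, levels = fit$container_levels)
  }
  tt <- stats::delete.response(stats::terms(fit$fixed_formula))
  X <- stats::model.matrix(tt, nd2)
  bhat <- lme4::fixef(fit$model)
  X <- X[, names(bhat), drop = FALSE]
  point <- drop(X %*% bhat)
  var_fix <- rowSums((X %*% as.matrix(stats::vcov(fit$model))) * X)

  re <- lme4::ranef(fit$model)
  # with the double-bar syntax lme4 splits the grouping factor; collect both
  re_int <- rep(0, length(fit$batches)); names(re_int) <- fit$batches
  re_slp <- re_int
  for (part in re) {
    if ("(Intercept)" %in% colnames(part)) {
      re_int[rownames(part)] <- re_int[rownames(part)] + part[, "(Intercept)"]
    }
    if ("time_months" %in% colnames(part)) {
      re_slp[rownames(part)] <- re_slp[rownames(part)] + part[, "time_months"]
    }
  }
  adj <- ifelse(new_flag, 0,
                re_int[newdata$batch_id] +
                  re_slp[newdata$batch_id] * newdata$time_months)
  var_new <- ifelse(new_flag,
                    fit$var_intercept +
                      fit$var_slope * newdata$time_months^2, 0)
  point <- point + ifelse(is.na(adj), 0, adj)
  se <- sqrt(var_fix + var_new + fit$sigma2)
  z <- stats::qnorm(1 - alpha / 2)
  out <- newdata
  out$alpha <- alpha
  out$kind <- "predictive"
  out$lower <- point - z * se
  out$center <- point
  out$upper <- point + z * se
  class(out) <- c("prediction_interval", "data.frame")
  out
}
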