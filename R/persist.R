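# Audit-trail persistence of posterior draws: a long CSV (one row per
# draw x parameter) plus a JSON metadata sidecar, reconstructable into a
# working posterior_draws object.

#' Save posterior draws to a directory
#'
#' Writes `draws.csv` (columnar text, one row per draw x parameter) and
#' `draws_meta.json` (index maps, priors, MCMC settings) so the fit can be
#' reloaded with [load_posterior_draws()] for prediction without refitting.
#'
#' @param draws a [fit_gibbs()] result.
#' @param dir output directory (created if absent).
#' @return `dir`, invisibly.
#' @export
save_posterior_draws <- function(draws, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_posterior_draws(draws, file.path(dir, "draws.csv"))
  meta <- list(types = draws$types, temps = draws$temps,
               batches = draws$batches,
               bt_levels = draws$bt_levels, btT_levels = draws$btT_levels,
               tT_levels = draws$tT_levels,
               batch_container = as.list(draws$batch_container),
               two_containers = draws$two_containers,
               slope_model = draws$spec$slope_model,
               priors = unclass(draws$priors),
               mcmc = unclass(draws$mcmc))
  jsonlite::write_json(meta, file.path(dir, "draws_meta.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Load posterior draws saved by [save_posterior_draws()]
#'
#' @param dir directory holding `draws.csv` and `draws_meta.json`.
#' @return a `posterior_draws` object.
#' @export
load_posterior_draws <- function(dir) {
  meta <- jsonlite::read_json(file.path(dir, "draws_meta.json"),
                              simplifyVector = TRUE)
  long <- utils::read.csv(file.path(dir, "draws.csv"),
                          stringsAsFactors = FALSE)
  pars <- unique(long$parameter)
  n_draws <- nrow(long) / length(pars)
  pm <- matrix(long$value, nrow = n_draws, ncol = length(pars),
               dimnames = list(NULL, pars))
  first <- long[seq_len(n_draws), ]

  grab <- function(base, levels_cr) {
    cols <- sprintf("%s[%s]", base,
                    gsub("\r", ":", levels_cr, fixed = TRUE))
    out <- pm[, cols, drop = FALSE]
    colnames(out) <- levels_cr
    out
  }
  temps <- as.numeric(meta$temps)
  draws <- list(
    mu_alpha = pm[, "mu_alpha"],
    gamma_syringe = if ("gamma_syringe" %in% pars) {
      pm[, "gamma_syringe"]
    } else rep(0, n_draws),
    a_type = grab("a", meta$types),
    alpha_bt = grab("alpha", meta$bt_levels),
    M_T = grab("M", as.character(temps)),
    m_tT = grab("m", meta$tT_levels),
    beta_btT = grab("beta", meta$btT_levels),
    variances = pm[, c("tau_a2", "sigma_a2", "tau_b2", "sigma_b2",
                       "sigma2")],
    arrhenius = if (all(c("log_A", "Ea_kJ") %in% pars)) {
      pm[, c("log_A", "Ea_kJ")]
    },
    chain = first$chain, iteration = first$iteration,
    types = meta$types, temps = temps, batches = meta$batches,
    bt_levels = meta$bt_levels, btT_levels = meta$btT_levels,
    tT_levels = meta$tT_levels,
    batch_container = unlist(meta$batch_container),
    two_containers = meta$two_containers,
    spec = model_spec(meta$slope_model),
    priors = do.call(prior_config, meta$priors),
    mcmc = do.call(mcmc_config, meta$mcmc))
  class(draws) <- "posterior_draws"
  draws
}
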