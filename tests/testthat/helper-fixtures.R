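# Shared fixtures: everything generated in code, no stored data files.

# small hand-written dataset: 2 batches x 2 types, two temperatures
tiny_records <- function() {
  expand.grid(batch_id = c("B1", "B2"), molecular_type = c("A", "B"),
              temperature_C = c(5, 25), time_months = c(0, 3, 6),
              KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE) |>
    transform(container = ifelse(batch_id == "B1", "vial", "syringe"),
              potency = 100 -
                (0.5 + 0.2 * (temperature_C == 25)) * time_months)
}

tiny_dataset <- function() stability_dataset(tiny_records())

# reduced cohort for fast hierarchical fits: 4 batches, 3 types
small_design <- function() {
  cohort_design(n_batches = 4L, container_split = c(syringe = 2L, vial = 2L),
                type_labels = c("A", "B", "C"))
}

fast_mcmc <- function(seed = 42L, n_chains = 1L) {
  mcmc_config(n_iterations = 1500L, burn_in = 400L, seed = seed,
              n_chains = n_chains)
}

# Monte-Carlo standard error by batch means (accounts for autocorrelation)
mcse <- function(x, n_batches = 25L) {
  bm <- tapply(x, cut(seq_along(x), n_batches, labels = FALSE), mean)
  stats::sd(bm) / sqrt(n_batches)
}

# noise-free single-stratum dataset on an exact line
line_dataset <- function(intercept = 100, slope = -1,
                         times = c(0, 1, 2, 3, 4, 6),
                         temperature = 5) {
  stability_dataset(data.frame(
    batch_id = "B1", molecular_type = "A", container = "vial",
    temperature_C = temperature, time_months = times,
    potency = intercept + slope * times))
}

# noise-free multi-batch cohort on a shared exact line; several batches so
# the between-batch variance components are identified (and collapse to ~0)
line_cohort <- function(intercept = 100, slope = -1, n_batches = 4L,
                        times = c(0, 1, 2, 3, 4, 6)) {
  rec <- expand.grid(batch_id = sprintf("B%d", seq_len(n_batches)),
                     time_months = times, KEEP.OUT.ATTRS = FALSE,
                     stringsAsFactors = FALSE)
  rec$molecular_type <- "A"
  rec$container <- "vial"
  rec$temperature_C <- 5
  rec$potency <- intercept + slope * rec$time_months
  stability_dataset(rec)
}
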