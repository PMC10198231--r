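# Shared fixtures for the tremorMPP suite. Everything is generated in code;
# sizes are scaled down where the tested property does not depend on scale
# (epoch duration for type-I error, cohort size for structural checks).

quiet_band <- band_definition()

# homogeneous-generator models (heterogeneity off) for calibration oracles
bm_fixed <- function(...) background_model(animal_logit_sd = 0, ...)
tm_fixed <- function(...) tremor_model(animal_sdlog = 0, epoch_sdlog = 0, ...)

# Gaussian MPP-level table: unit-test fixture for the rm_stats module whose
# contract is on tables, not traces. Cell means given per dose x epoch.
make_mpp_table <- function(n_per_dose = 6, doses = c(0, 1),
                           epochs = c("B", "H1", "E1"),
                           cell_means = NULL, sd_animal = 5, sd_resid = 2,
                           genotype = "WT", drug = "drugX", seed = 1) {
  set.seed(seed)
  nd <- length(doses); ne <- length(epochs)
  if (is.null(cell_means))
    cell_means <- matrix(50, nd, ne)
  rows <- list()
  for (d in seq_len(nd)) for (a in seq_len(n_per_dose)) {
    u <- rnorm(1, sd = sd_animal)
    id <- sprintf("m_d%d_a%02d", d, a)
    for (e in seq_len(ne)) {
      rows[[length(rows) + 1L]] <- data.frame(
        animal_id = id, genotype = genotype, drug = drug, dose = doses[d],
        epoch = epochs[e],
        mpp = cell_means[d, e] + u + rnorm(1, sd = sd_resid),
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

welch_band_fraction <- function(trace) {
  ps <- estimate_psd(trace)
  band_power(ps, quiet_band$tremor_lo, quiet_band$tremor_hi) /
    band_power(ps, quiet_band$total_lo, quiet_band$total_hi)
}
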