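#' Calibration summaries of the default generator
#'
#' Two reference quantities of the default stated world, computed end to end
#' through the simulation and Welch/MPP pipeline:
#' \describe{
#'   \item{`baseline_mpp_mean`}{mean per-animal MPP across simulated drug-free
#'     baseline (B) epochs: the in-band power a tremor-free animal shows "by
#'     chance" plus baseline in-band structure; calibrated to the published
#'     30-35% range.}
#'   \item{`harmaline_mpp_mean`}{mean per-animal MPP across simulated
#'     harmaline pre-treatment epochs (H1, H2) with the default tremor
#'     variance ratio; calibrated to the published 75-83% range.}
#' }
#' Both average `n_animals` animals per master seed over `n_seeds` master
#' seeds, with per-animal seeds derived exactly as in [simulate_cohort()].
#'
#' @param n_animals Animals per master seed (default 12, one dose group).
#' @param n_seeds Master seeds averaged over (default 10).
#' @param duration_s Epoch duration (default 900 s).
#' @param sample_rate_hz Sampling rate (default 128 Hz).
#' @param master_seed First master seed; seeds `master_seed + 0:(n_seeds-1)`
#'   are used.
#' @param background,tremor Generator models (defaults = the calibrated
#'   stated world).
#' @return Mean MPP in percent.
#' @export
baseline_mpp_mean <- function(n_animals = 12, n_seeds = 10, duration_s = 900,
                              sample_rate_hz = 128, master_seed = 1,
                              background = background_model(),
                              tremor = tremor_model()) {
  epoch_mpp_mean("B", n_animals, n_seeds, duration_s, sample_rate_hz,
                 master_seed, background, tremor)
}

#' @rdname baseline_mpp_mean
#' @export
harmaline_mpp_mean <- function(n_animals = 12, n_seeds = 10, duration_s = 900,
                               sample_rate_hz = 128, master_seed = 1,
                               background = background_model(),
                               tremor = tremor_model()) {
  epoch_mpp_mean(c("H1", "H2"), n_animals, n_seeds, duration_s,
                 sample_rate_hz, master_seed, background, tremor)
}

epoch_mpp_mean <- function(epochs, n_animals, n_seeds, duration_s,
                           sample_rate_hz, master_seed, background, tremor) {
  sched <- epoch_schedule(epochs, duration_s)
  drug <- drug_model("alcohol")   # dose 0: no drug effect anywhere
  vals <- vapply(seq_len(n_seeds), function(k) {
    master <- master_seed + k - 1
    per_animal <- vapply(seq_len(n_animals), function(a) {
      child <- derive_seed(master, 1e6 + 1e4 + a)
      sess <- simulate_session(genotype("WT"), 0, drug, sched, background,
                               tremor, sample_rate_hz,
                               animal_id = sprintf("a%02d", a), seed = child)
      mean(vapply(sess, function(tr) compute_mpp(tr)$mpp, numeric(1)))
    }, numeric(1))
    mean(per_animal)
  }, numeric(1))
  mean(vals)
}
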