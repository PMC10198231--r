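test_that("flat-spectrum chance fraction matches direct arithmetic", {
  expect_equal(flat_spectrum_chance_fraction(9, 16, 0.25, 32), 7 / 31.75)
  expect_equal(flat_spectrum_chance_fraction(0.25, 32, 0.25, 32), 1.0)
  expect_lt(flat_spectrum_chance_fraction(9, 9.000001, 0.25, 32), 1e-6)
  expect_error(flat_spectrum_chance_fraction(16, 9, 0.25, 32), "invalid band")
  expect_error(flat_spectrum_chance_fraction(0.1, 16, 0.25, 32), "invalid band")
})

test_that("model constructors enforce their invariants", {
  chance <- flat_spectrum_chance_fraction(9, 16, 0.25, 32)
  expect_error(background_model(in_band_fraction = chance - 0.01), "strictly")
  expect_error(background_model(in_band_fraction = 1), "strictly")
  expect_silent(background_model(in_band_fraction = 0.2205)) # just above chance
  expect_error(background_model(total_variance = -1), "nonnegative")
  expect_error(tremor_model(center_hz = 16, bandwidth_hz = 4), "within")
  expect_error(tremor_model(variance_ratio = -1), ">= 0")
  expect_error(drug_model("alcohol", dose_levels = c(0, -1, 2)))
  expect_error(drug_model("alcohol", active_epochs = c("B")), "subset")
  expect_error(drug_model("nosuchdrug"), "unknown drug")
  expect_error(genotype("KO", drug_responsive = TRUE), "cannot")
  expect_false(genotype("KO")$drug_responsive)
  expect_error(epoch_schedule(c("E1", "B")), "canonical order")
  expect_error(epoch_schedule(c("B", "B")), "unique")
  expect_error(cohort_design(drug_model("alcohol"), group_sizes = 1),
               ">= 2 animals")
})

test_that("background generator hits variance and in-band calibration", {
  # f at the chance value boundary: pure flat spectrum
  tr <- simulate_background(900, 128, bm_fixed(in_band_fraction = 0.2205),
                            seed = 101)
  expect_equal(welch_band_fraction(tr), 0.2205, tolerance = 0.02 / 0.2205)
  # default mixture
  tr <- simulate_background(900, 128, bm_fixed(), seed = 102)
  expect_equal(welch_band_fraction(tr), 0.32, tolerance = 0.02 / 0.32)
  expect_equal(var(tr$samples), 1, tolerance = 0.05)
  # zero variance -> all-zero trace
  z <- simulate_background(10, 128, bm_fixed(total_variance = 0))
  expect_true(all(z$samples == 0))
  expect_error(simulate_background(10, 128, bm_fixed(),
                                   in_band_fraction = 0.1), "chance")
})

test_that("tremor component is band-limited with calibrated variance", {
  tr0 <- simulate_tremor(60, 128, 1, tm_fixed(), suppression = 1)
  expect_true(all(tr0$samples == 0))
  tr <- simulate_tremor(900, 128, 1, tm_fixed(), suppression = 0, seed = 103)
  expect_equal(var(tr$samples), 2.24, tolerance = 0.05)
  # >= 99% of realized power inside 9-16 Hz (periodogram integration oracle)
  tr <- simulate_tremor(300, 128, 1,
                        tm_fixed(center_hz = 12, bandwidth_hz = 3), seed = 104)
  ps <- periodogram_psd(tr)
  expect_gte(band_power(ps, 9, 16) / band_power(ps, 0.001, 64), 0.99)
  expect_error(simulate_tremor(60, 128, 1, tm_fixed(), suppression = 1.2),
               "suppression")
})

test_that("effect multiplier follows the gated Hill curve", {
  alc <- drug_model("alcohol")
  gnx <- drug_model("ganaxolone")
  wt <- genotype("WT"); ko <- genotype("KO")
  expect_identical(effect_multiplier(alc, 0, "E1", wt), 0)
  # pre-treatment epochs never suppressed
  for (ep in c("B", "H1", "H2"))
    expect_identical(effect_multiplier(alc, 0.575, ep, wt), 0)
  # alcohol clears after E1; ganaxolone persists; KO never responds
  expect_identical(effect_multiplier(alc, 0.575, "E3", wt), 0)
  expect_gt(effect_multiplier(gnx, 10, "E4", wt), 0)
  expect_identical(effect_multiplier(gnx, 10, "E4", ko), 0)
  # Hill formula against direct arithmetic
  s <- effect_multiplier(gnx, 7, "E2", wt)
  expect_equal(s, 0.8 * 7^8 / (5^8 + 7^8), tolerance = 1e-12)
  # nondecreasing in dose
  doses <- seq(0, 0.7, by = 0.05)
  supp <- vapply(doses, function(d) effect_multiplier(alc, d, "E1", wt),
                 numeric(1))
  expect_true(all(diff(supp) >= 0))
  expect_error(effect_multiplier(alc, -1, "E1", wt), "dose")
  expect_error(effect_multiplier(alc, 0.5, "X9", wt), "epoch")
})

test_that("session structure: baseline clean, harmaline additive, drug scaled", {
  alc <- drug_model("alcohol")
  # schedule with only B: single tremor-free trace
  s <- simulate_session(genotype("WT"), 0.575, alc,
                        epoch_schedule("B", 120), bm_fixed(), tm_fixed(),
                        seed = 7)
  expect_length(s, 1L)
  expect_lt(welch_band_fraction(s$B), 0.45)
  # variance additivity at an H epoch, 900 s, heterogeneity off
  s <- simulate_session(genotype("WT"), 0, alc,
                        epoch_schedule(c("B", "H1"), 900),
                        bm_fixed(), tm_fixed(), seed = 8)
  expect_equal(var(s$H1$samples), 1 + 2.24, tolerance = 0.05)
  expect_equal(var(s$B$samples), 1, tolerance = 0.05)
  # closed-form MPP expectation: E[MPP] = 100 (f B + T)/(B + T)
  f <- 0.32; Tv <- 2.24
  mpps <- vapply(1:6, function(i) {
    s <- simulate_session(genotype("WT"), 0, alc,
                          epoch_schedule(c("B", "H1"), 300),
                          bm_fixed(), tm_fixed(), seed = 200 + i)
    compute_mpp(s$H1)$mpp
  }, numeric(1))
  expect_equal(mean(mpps), 100 * (f + Tv) / (1 + Tv), tolerance = 2 / 79)
  # drug scaling: suppressed E1 tremor variance
  dose <- 0.575
  supp <- effect_multiplier(alc, dose, "E1", genotype("WT"))
  s <- simulate_session(genotype("WT"), dose, alc,
                        epoch_schedule(c("B", "H1", "E1"), 900),
                        bm_fixed(), tm_fixed(), seed = 9)
  expect_equal(var(s$E1$samples), 1 + 2.24 * (1 - supp), tolerance = 0.05)
})

test_that("cohort simulation is deterministic and correctly sized", {
  d <- cohort_design(drug_model("alcohol"),
                     list(genotype("WT")),
                     group_sizes = matrix(c(11, 11, 12, 11), 1),
                     schedule = epoch_schedule(c("B", "H1"), 30),
                     master_seed = 42)
  co1 <- simulate_cohort(d)
  co2 <- simulate_cohort(d)
  expect_identical(co1$traces, co2$traces)       # bit-identical regeneration
  expect_equal(nrow(co1$manifest), 45)           # 11+11+12+11 per genotype
  expect_length(co1$traces, 45 * 2)
  expect_false(anyDuplicated(co1$manifest$animal_id) > 0)
  expect_gt(length(unique(co1$manifest$seed)), 40)  # per-animal child seeds
  # seeds independent of other groups' sizes
  d2 <- cohort_design(drug_model("alcohol"), list(genotype("WT")),
                      group_sizes = matrix(c(5, 11, 12, 11), 1),
                      schedule = epoch_schedule(c("B", "H1"), 30),
                      master_seed = 42)
  m1 <- co1$manifest; m2 <- simulate_cohort(d2)$manifest
  shared <- intersect(m1$animal_id, m2$animal_id)
  expect_identical(m1$seed[match(shared, m1$animal_id)],
                   m2$seed[match(shared, m2$animal_id)])
  # empty genotype list -> empty collection, valid manifest
  e <- simulate_cohort(cohort_design(drug_model("alcohol"), list(),
                                     group_sizes = 12))
  expect_length(e$traces, 0)
  expect_identical(nrow(e$manifest), 0L)
})

test_that("genotype null: treated KO MPP matches vehicle distribution", {
  alc <- drug_model("alcohol")
  sched <- epoch_schedule(c("B", "H1", "E1"), 60)
  sim_e1 <- function(geno, dose, seeds) vapply(seeds, function(s) {
    sess <- simulate_session(geno, dose, alc, sched, background_model(),
                             tremor_model(), seed = s)
    compute_mpp(sess$E1)$mpp
  }, numeric(1))
  ko <- sim_e1(genotype("KO"), 0.575, 1:100)
  veh <- sim_e1(genotype("WT"), 0, 201:300)
  expect_gt(suppressWarnings(stats::ks.test(ko, veh)$p.value), 0.01)
})
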