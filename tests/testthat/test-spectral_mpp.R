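sine_trace <- function(freq, duration_s = 120, fs = 128, amp = 1) {
  t <- seq(0, duration_s - 1 / fs, by = 1 / fs)
  motion_trace(amp * sin(2 * pi * freq * t), fs, epoch = "H1",
               animal_id = "sine")
}

test_that("PSD estimator satisfies Parseval and localises a sinusoid", {
  tr <- sine_trace(12, 900)
  ps <- estimate_psd(tr)
  expect_true(all(ps$power >= 0))
  expect_lte(ps$resolution_hz, 0.25)
  total <- band_power(ps, ps$resolution_hz / 2, 64)
  expect_equal(total, 0.5, tolerance = 0.02)          # sine variance = A^2/2
  expect_gt(band_power(ps, 11.5, 12.5) / total, 0.99) # mass at 12 Hz
  # white noise: flat at sigma^2 / 64 over (0, 64], Parseval within 2%
  set.seed(5)
  wn <- motion_trace(rnorm(900 * 128, sd = 2), 128)
  psw <- estimate_psd(wn)
  expect_equal(band_power(psw, psw$resolution_hz / 2, 64), 4, tolerance = 0.02)
  mid <- psw$frequencies > 1 & psw$frequencies < 63
  expect_equal(mean(psw$power[mid]), 4 / 64, tolerance = 0.02)
  # zero signal -> all-zero PSD
  expect_true(all(estimate_psd(motion_trace(numeric(2048), 128))$power == 0))
  # determinism
  expect_identical(estimate_psd(wn), estimate_psd(wn))
})

test_that("PSD estimator rejects bad input", {
  expect_error(estimate_psd(sine_trace(12, 4)), "insufficient data")
  expect_error(estimate_psd(sine_trace(12), window_length_s = 2), ">= 4")
  expect_error(estimate_psd(sine_trace(12), overlap_fraction = 1), "overlap")
  tr <- sine_trace(12)
  tr$samples[5] <- NA
  expect_error(estimate_psd(tr), "non-finite")
  expect_error(motion_trace(c(1, NA, 3)), "non-finite")
})

test_that("band power integrates correctly and is exactly additive", {
  ps <- estimate_psd(sine_trace(12, 300))
  expect_equal(band_power(ps, 9, 16), 0.5, tolerance = 0.02)
  expect_lt(band_power(ps, 17, 32), 1e-3)
  # disjoint sub-bands partition the total exactly (bin-aligned edges)
  set.seed(6)
  psw <- estimate_psd(motion_trace(rnorm(128 * 60), 128))
  df <- psw$resolution_hz
  lhs <- band_power(psw, 0.25, 9 - df) + band_power(psw, 9, 16) +
    band_power(psw, 16 + df, 32)
  expect_equal(lhs, band_power(psw, 0.25, 32), tolerance = 1e-12)
  expect_error(band_power(psw, 16, 9), "invalid band")
  expect_error(band_power(psw, 10, 100), "invalid band")
})

test_that("MPP matches its analytic oracles", {
  expect_gte(compute_mpp(sine_trace(12))$mpp, 99)
  expect_lte(compute_mpp(sine_trace(4))$mpp, 1)
  set.seed(11)
  wn <- motion_trace(rnorm(900 * 128), 128)
  expect_equal(compute_mpp(wn)$mpp, 100 * 7 / 31.75, tolerance = 1.0 / 22)
  expect_error(compute_mpp(motion_trace(numeric(128 * 120), 128)),
               "undefined statistic")
  expect_error(compute_mpp(sine_trace(12, 30)), "too short")
})

test_that("MPP is bounded, amplitude-invariant and band-monotone", {
  set.seed(12)
  for (i in 1:40) {
    lo <- runif(1, 0.5, 30); hi <- lo + runif(1, 0.5, 62 - lo)
    x <- band_noise(128 * 64, 128, lo, hi, runif(1, 0.1, 10)) +
      rnorm(128 * 64, sd = 0.1)
    tr <- motion_trace(x, 128)
    m <- compute_mpp(tr)
    expect_gte(m$mpp, 0); expect_lte(m$mpp, 100)
    scaled <- motion_trace(x * runif(1, 0.01, 100), 128)
    expect_equal(compute_mpp(scaled)$mpp, m$mpp, tolerance = 1e-10)
    # adding a strictly 9-16 Hz component raises MPP
    extra <- band_noise(128 * 64, 128, 9.5, 14, 2)
    expect_gt(compute_mpp(motion_trace(x + extra, 128))$mpp, m$mpp)
  }
})

test_that("Welch MPP agrees with the full-length periodogram oracle", {
  for (seed in 1:3) {
    s <- simulate_session(genotype("WT"), 0, drug_model("alcohol"),
                          epoch_schedule(c("B", "H1"), 900),
                          background_model(), tremor_model(), seed = seed)
    for (tr in s) {
      ps <- periodogram_psd(tr)
      ref <- 100 * band_power(ps, 9, 16) / band_power(ps, 0.25, 32)
      expect_equal(compute_mpp(tr)$mpp, ref, tolerance = 1.5 / ref)
    }
  }
})

test_that("mpp_table is tidy, ordered and guards against duplicates", {
  d <- cohort_design(drug_model("alcohol"), list(genotype("WT")),
                     group_sizes = 2, schedule = epoch_schedule(duration_s = 64),
                     master_seed = 3)
  co <- simulate_cohort(d)
  tab <- mpp_table(co$traces)
  expect_equal(nrow(tab), 8 * 7)          # animals x epochs
  expect_identical(tab$epoch[1:7], c("B", "H1", "H2", "E1", "E2", "E3", "E4"))
  expect_false(is.unsorted(tab$animal_id))
  # one trace -> one row consistent with compute_mpp
  one <- mpp_table(co$traces[1])
  expect_identical(one$mpp, compute_mpp(co$traces[[1]])$mpp)
  # duplicates rejected
  expect_error(mpp_table(c(co$traces[1], co$traces[1])), "duplicate")
  # empty input -> empty table with full header
  empty <- mpp_table(list())
  expect_identical(nrow(empty), 0L)
  expect_identical(names(empty), names(tab))
})
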