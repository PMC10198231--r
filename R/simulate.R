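#' Motion trace container
#'
#' One recorded (or simulated) epoch of the load-sensor signal, uniformly
#' sampled, with the metadata the downstream statistics need.
#'
#' @param samples Numeric vector of force values, arbitrary units; all finite.
#' @param sample_rate_hz Sampling rate; the study hardware samples at 128 Hz.
#' @param animal_id,genotype,drug,dose,epoch,seed Provenance metadata.
#' @return A `motion_trace` object.
#' @export
motion_trace <- function(samples, sample_rate_hz = 128, animal_id = NA_character_,
                         genotype = NA_character_, drug = NA_character_,
                         dose = NA_real_, epoch = NA_character_,
                         seed = NA_integer_) {
  samples <- as.numeric(samples)
  if (length(samples) == 0) stop("empty trace", call. = FALSE)
  if (any(!is.finite(samples)))
    stop("trace contains non-finite samples", call. = FALSE)
  if (sample_rate_hz <= 0) stop("sample_rate_hz must be > 0", call. = FALSE)
  structure(list(samples = samples, sample_rate_hz = sample_rate_hz,
                 animal_id = animal_id, genotype = genotype, drug = drug,
                 dose = dose, epoch = epoch, seed = seed),
            class = "motion_trace")
}

#' @export
print.motion_trace <- function(x, ...) {
  cat(sprintf("<motion_trace> %s %s %s dose=%s epoch=%s: %d samples @ %g Hz (%.1f s)\n",
              x$animal_id, x$genotype, x$drug, format(x$dose), x$epoch,
              length(x$samples), x$sample_rate_hz,
              length(x$samples) / x$sample_rate_hz))
  invisible(x)
}

trace_duration <- function(trace) length(trace$samples) / trace$sample_rate_hz

# Stationary Gaussian noise with a flat power spectrum on [lo, hi] Hz and
# expected variance `variance`, synthesised in the frequency domain: complex
# Gaussian coefficients on the in-band FFT bins, Hermitian-symmetrised,
# inverse transformed. All realised power lies inside the band by
# construction. Returns a length-n real vector.
band_noise <- function(n, fs, lo, hi, variance) {
  band_noise_multi(n, fs, list(c(lo, hi)), variance)
}

# Several independent flat-band components synthesised in a single inverse
# FFT (their Gaussian spectral coefficients simply add, also on overlapping
# bins). `bands` is a list of c(lo, hi); `variances` one variance per band.
band_noise_multi <- function(n, fs, bands, variances) {
  keep <- variances > 0
  bands <- bands[keep]; variances <- variances[keep]
  if (length(bands) == 0) return(numeric(n))
  freq <- (seq_len(n %/% 2)) * fs / n          # positive-frequency bins
  spec_var <- numeric(length(freq))            # per-bin coefficient variance
  for (k in seq_along(bands)) {
    sel <- freq >= bands[[k]][1] & freq <= bands[[k]][2] & freq < fs / 2
    m <- sum(sel)
    if (m == 0)
      stop("band too narrow for the frequency resolution", call. = FALSE)
    # each bin and its conjugate contribute 2*sigma^2/n^2 each to Var(x_t)
    spec_var[sel] <- spec_var[sel] + n^2 * variances[k] / (4 * m)
  }
  sel <- which(spec_var > 0)
  sigma <- sqrt(spec_var[sel])
  m <- length(sel)
  z <- rnorm(m, sd = sigma) + (0+1i) * rnorm(m, sd = sigma)
  X <- rep(0+0i, n)
  X[sel + 1L] <- z
  X[n + 1L - sel] <- Conj(z)
  Re(fft(X, inverse = TRUE)) / n
}

#' Simulate tremor-free background motion
#'
#' Draws one epoch of spontaneous locomotion/background signal from a
#' [background_model()]: a flat spectral component over the full analysis
#' band mixed with a band-limited tremor-band component, weighted so the
#' expected in-band power fraction equals the model's `in_band_fraction`.
#'
#' @param duration_s Epoch duration, seconds.
#' @param sample_rate_hz Sampling rate, Hz (default 128).
#' @param model A [background_model()].
#' @param in_band_fraction Optional override of the model's fraction (used
#'   internally for per-animal heterogeneity).
#' @param seed Optional integer seed; if `NULL` the current RNG state is used.
#' @return A [motion_trace()].
#' @export
simulate_background <- function(duration_s, sample_rate_hz = 128,
                                model = background_model(),
                                in_band_fraction = NULL, seed = NULL) {
  stopifnot(inherits(model, "background_model"), duration_s > 0)
  if (!is.null(seed)) set.seed(seed)
  f <- if (is.null(in_band_fraction)) model$in_band_fraction else in_band_fraction
  chance <- model$chance_fraction
  if (!(f > chance && f < 1))
    stop("in_band_fraction outside (chance, 1): cannot calibrate mixture",
         call. = FALSE)
  n <- round(duration_s * sample_rate_hz)
  V <- model$total_variance
  if (V == 0)
    return(motion_trace(numeric(n), sample_rate_hz, seed = seed %||% NA_integer_))
  b <- model$band
  w <- (f - chance) / (1 - chance)   # weight of the in-band component
  x <- band_noise_multi(n, sample_rate_hz,
                        list(c(b$total_lo, b$total_hi),
                             c(b$tremor_lo, b$tremor_hi)),
                        c((1 - w) * V, w * V))
  motion_trace(x, sample_rate_hz, seed = seed %||% NA_integer_)
}

#' Simulate the harmaline tremor component
#'
#' Band-limited Gaussian noise confined to the tremor model's spectral
#' support, with variance
#' `variance_ratio * background_variance * (1 - suppression)`.
#'
#' @param duration_s Seconds.
#' @param sample_rate_hz Hz.
#' @param background_variance Background total variance the ratio refers to.
#' @param model A [tremor_model()].
#' @param suppression Fractional drug suppression of tremor variance, `[0, 1]`.
#' @param variance_ratio Optional override of the model's ratio (per-animal
#'   heterogeneity hook).
#' @param seed Optional integer seed.
#' @return A [motion_trace()]; all-zero when the effective variance is 0.
#' @export
simulate_tremor <- function(duration_s, sample_rate_hz = 128,
                            background_variance = 1, model = tremor_model(),
                            suppression = 0, variance_ratio = NULL,
                            seed = NULL) {
  stopifnot(inherits(model, "tremor_model"), duration_s > 0)
  if (suppression < 0 || suppression > 1)
    stop("suppression must be in [0, 1]", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  r <- if (is.null(variance_ratio)) model$variance_ratio else variance_ratio
  v <- r * background_variance * (1 - suppression)
  n <- round(duration_s * sample_rate_hz)
  if (v == 0) return(motion_trace(numeric(n), sample_rate_hz))
  x <- band_noise(n, sample_rate_hz, model$support[1], model$support[2], v)
  motion_trace(x, sample_rate_hz)
}

#' Fractional tremor suppression for a design cell
#'
#' Applies the drug's Hill/Emax curve, gated by epoch and genotype: no
#' suppression before treatment (B, H1, H2), none outside the drug's active
#' epochs (clearance), and none in non-responsive (KO) animals.
#'
#' @param drug A [drug_model()].
#' @param dose Nonnegative dose in the drug's units.
#' @param epoch_label One of the canonical epoch labels.
#' @param genotype A [genotype()].
#' @return Fractional suppression in `[0, 1]`.
#' @examples
#' effect_multiplier(drug_model("alcohol"), 0.575, "E1", genotype("WT"))
#' effect_multiplier(drug_model("alcohol"), 0.575, "E3", genotype("WT")) # 0
#' @export
effect_multiplier <- function(drug, dose, epoch_label, genotype) {
  stopifnot(inherits(drug, "drug_model"), inherits(genotype, "genotype"))
  if (!is.finite(dose) || dose < 0) stop("dose must be >= 0", call. = FALSE)
  if (!epoch_label %in% EPOCH_LEVELS)
    stop("unknown epoch label: ", epoch_label, call. = FALSE)
  if (dose == 0 || !genotype$drug_responsive) return(0)
  if (!epoch_label %in% drug$active_epochs) return(0)
  dh <- dose^drug$hill
  drug$emax * dh / (drug$ed50^drug$hill + dh)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Deterministic child-seed derivation: mixes the master seed with a
# position-based counter so seeds do not depend on other groups' sizes.
derive_seed <- function(master_seed, counter) {
  as.integer((((as.numeric(master_seed) %% 65521) + 1) * 2654435761 +
                counter * 97003) %% 2147483563)
}

#' Simulate one animal's full session
#'
#' Generates one [motion_trace()] per scheduled epoch for a single animal in
#' one (genotype, dose) cell. The baseline epoch carries no tremor; H1/H2
#' carry the full tremor; E1-E4 tremor is scaled by
#' `1 - effect_multiplier(...)`. Animal-level heterogeneity (in-band
#' fraction, tremor variance multiplier) is drawn once at session start,
#' epoch-level tremor jitter per epoch.
#'
#' @param genotype A [genotype()].
#' @param dose Dose administered.
#' @param drug A [drug_model()].
#' @param schedule An [epoch_schedule()].
#' @param background A [background_model()].
#' @param tremor A [tremor_model()].
#' @param sample_rate_hz Hz.
#' @param animal_id Identifier stamped on the traces.
#' @param seed Optional per-animal seed (sets the RNG for the whole session).
#' @param hardware_filter If `TRUE`, apply a 2nd-order Butterworth emulation
#'   of the 1-70 Hz amplifier passband to each trace (70 Hz being above the
#'   64 Hz Nyquist, only the 1 Hz high-pass edge is realisable). Default
#'   `FALSE`: the analysis band starts at 0.25 Hz, below the hardware
#'   high-pass, so the clean generative path is the default.
#' @return Named list of [motion_trace()], one per epoch.
#' @export
simulate_session <- function(genotype, dose, drug, schedule = epoch_schedule(),
                             background = background_model(),
                             tremor = tremor_model(), sample_rate_hz = 128,
                             animal_id = "animal", seed = NULL,
                             hardware_filter = FALSE) {
  stopifnot(inherits(schedule, "epoch_schedule"))
  if (!is.null(seed)) set.seed(seed)
  # animal-level random effects
  f_i <- background$in_band_fraction
  if (background$animal_logit_sd > 0 && background$total_variance > 0) {
    f_i <- plogis(qlogis(f_i) + rnorm(1, sd = background$animal_logit_sd))
    f_i <- min(max(f_i, background$chance_fraction + 1e-4), 1 - 1e-4)
  }
  r_i <- tremor$variance_ratio
  if (tremor$animal_sdlog > 0) r_i <- r_i * exp(rnorm(1, sd = tremor$animal_sdlog))
  out <- vector("list", nrow(schedule))
  names(out) <- schedule$label
  for (k in seq_len(nrow(schedule))) {
    ep <- schedule$label[k]
    dur <- schedule$duration_s[k]
    bg <- simulate_background(dur, sample_rate_hz, background,
                              in_band_fraction = f_i)
    if (ep == "B") {
      x <- bg$samples
    } else {
      r_ik <- r_i
      if (tremor$epoch_sdlog > 0) r_ik <- r_ik * exp(rnorm(1, sd = tremor$epoch_sdlog))
      supp <- effect_multiplier(drug, dose, ep, genotype)
      tr <- simulate_tremor(dur, sample_rate_hz, background$total_variance,
                            tremor, suppression = supp,
                            variance_ratio = r_ik)
      x <- bg$samples + tr$samples
    }
    if (hardware_filter) x <- butter2_bandpass(x, sample_rate_hz, 1, 70)
    out[[k]] <- motion_trace(x, sample_rate_hz, animal_id = animal_id,
                             genotype = genotype$label, drug = drug$name,
                             dose = dose, epoch = ep,
                             seed = seed %||% NA_integer_)
  }
  out
}

#' Simulate a full cohort
#'
#' Runs [simulate_session()] for every animal of every (genotype, dose) cell
#' of a [cohort_design()]. Per-animal seeds are derived deterministically
#' from the design's master seed, so regeneration with the same master seed
#' is bit-identical and independent of other groups' sizes.
#'
#' @param design A [cohort_design()].
#' @param hardware_filter Passed to [simulate_session()].
#' @return A `tremor_cohort` list with elements `traces` (flat named list of
#'   [motion_trace()], names `<animal_id>.<epoch>`) and `manifest` (data
#'   frame: animal_id, genotype, drug, dose, group, seed).
#' @export
simulate_cohort <- function(design, hardware_filter = FALSE) {
  stopifnot(inherits(design, "cohort_design"))
  traces <- list()
  man <- list()
  doses <- design$drug$dose_levels
  for (g in seq_along(design$genotypes)) {
    geno <- design$genotypes[[g]]
    for (d in seq_along(doses)) {
      n <- design$group_sizes[g, d]
      for (a in seq_len(n)) {
        counter <- g * 1e6 + d * 1e4 + a
        child <- derive_seed(design$master_seed, counter)
        id <- sprintf("%s_%s_d%d_a%02d", design$drug$name, geno$label, d, a)
        sess <- simulate_session(geno, doses[d], design$drug,
                                 design$schedule, design$background,
                                 design$tremor, animal_id = id, seed = child,
                                 hardware_filter = hardware_filter)
        names(sess) <- paste(id, names(sess), sep = ".")
        traces <- c(traces, sess)
        man[[length(man) + 1L]] <- data.frame(
          animal_id = id, genotype = geno$label, drug = design$drug$name,
          dose = doses[d], group = d, seed = child, stringsAsFactors = FALSE)
      }
    }
  }
  manifest <- if (length(man)) do.call(rbind, man) else
    data.frame(animal_id = character(), genotype = character(),
               drug = character(), dose = numeric(), group = integer(),
               seed = integer(), stringsAsFactors = FALSE)
  if (anyDuplicated(manifest$animal_id))
    stop("duplicate animal ids in manifest", call. = FALSE)
  structure(list(traces = traces, manifest = manifest, design = design),
            class = "tremor_cohort")
}

# 2nd-order Butterworth band-pass emulation of the acquisition amplifier,
# as cascaded RBJ-biquad high-pass and (when realisable) low-pass sections.
butter2_bandpass <- function(x, fs, lo, hi) {
  biquad <- function(x, b, a) {
    # direct-form II transposed
    y <- numeric(length(x)); z1 <- 0; z2 <- 0
    for (i in seq_along(x)) {
      y[i] <- b[1] * x[i] + z1
      z1 <- b[2] * x[i] - a[2] * y[i] + z2
      z2 <- b[3] * x[i] - a[3] * y[i]
    }
    y
  }
  coefs <- function(f0, fs, type) {
    w0 <- 2 * pi * f0 / fs
    q <- 1 / sqrt(2)
    alpha <- sin(w0) / (2 * q)
    cw <- cos(w0)
    if (type == "hp") b <- c((1 + cw) / 2, -(1 + cw), (1 + cw) / 2)
    else b <- c((1 - cw) / 2, 1 - cw, (1 - cw) / 2)
    a <- c(1 + alpha, -2 * cw, 1 - alpha)
    list(b = b / a[1], a = a / a[1])
  }
  hp <- coefs(lo, fs, "hp")
  x <- biquad(x, hp$b, hp$a)
  if (hi < fs / 2) {
    lp <- coefs(hi, fs, "lp")
    x <- biquad(x, lp$b, lp$a)
  }
  x
}
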