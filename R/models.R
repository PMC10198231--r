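#' Background (locomotion) spectral model
#'
#' Tremor-free motion on the platform is modelled as a two-component Gaussian
#' mixture in the frequency domain: a broadband flat component spanning the
#' full analysis band plus a band-limited component confined to the tremor
#' band. The mixing weight is chosen so the expected fraction of background
#' power inside the tremor band equals `in_band_fraction`; a purely flat
#' spectrum would put only the chance fraction (~0.2205 for 9-16 in
#' 0.25-32 Hz) there, and published baseline MPP runs 30-35%, so some
#' baseline in-band structure is required.
#'
#' Between-animal heterogeneity: each simulated animal draws its own in-band
#' fraction from a logit-normal distribution centred on `in_band_fraction`
#' with `animal_logit_sd` on the logit scale (0 disables heterogeneity).
#'
#' @param total_variance Total signal variance, arbitrary units squared.
#' @param in_band_fraction Expected fraction of background power inside the
#'   tremor band; must lie strictly between the flat-spectrum chance value
#'   and 1. Default 0.32 (midpoint of the 30-35% baseline range).
#' @param animal_logit_sd Between-animal SD of the in-band fraction on the
#'   logit scale. Default 0.25, calibrated so simulated baseline group means
#'   span roughly 30-35%.
#' @param band [band_definition()] giving the tremor and total bands.
#' @return A `background_model` object.
#' @export
background_model <- function(total_variance = 1, in_band_fraction = 0.32,
                             animal_logit_sd = 0.25,
                             band = band_definition()) {
  stopifnot(inherits(band, "band_definition"))
  chance <- flat_spectrum_chance_fraction(band$tremor_lo, band$tremor_hi,
                                          band$total_lo, band$total_hi)
  if (!is.finite(total_variance) || total_variance < 0)
    stop("total_variance must be nonnegative", call. = FALSE)
  if (!(in_band_fraction > chance && in_band_fraction < 1))
    stop(sprintf(
      "in_band_fraction must lie strictly in (chance = %.5f, 1); got %g",
      chance, in_band_fraction), call. = FALSE)
  if (animal_logit_sd < 0) stop("animal_logit_sd must be >= 0", call. = FALSE)
  structure(list(total_variance = total_variance,
                 in_band_fraction = in_band_fraction,
                 animal_logit_sd = animal_logit_sd,
                 band = band, chance_fraction = chance),
            class = "background_model")
}

#' Harmaline tremor component model
#'
#' The tremor is band-limited Gaussian noise (not a pure sinusoid: harmaline
#' tremor shows cycle-to-cycle frequency variability) with spectral support
#' `[center_hz - bandwidth_hz/2, center_hz + bandwidth_hz/2]`, which must sit
#' inside the 9-16 Hz tremor band. Its variance is `variance_ratio` times the
#' background total variance; `variance_ratio = 0` reproduces the tremor-free
#' baseline exactly. The default 2.24 inverts the closed-form MPP expectation
#' 100 * (f*B + T) / (B + T) at the midpoint (79%) of the published 75-83%
#' harmaline range, given the default background in-band fraction 0.32.
#'
#' Heterogeneity: each animal scales its tremor variance by a lognormal
#' factor with log-SD `animal_sdlog` (median 1), and every epoch applies an
#' additional lognormal jitter with log-SD `epoch_sdlog` so that repeated
#' epochs of one animal are correlated but not identical. Both default to
#' values derived from the spread of published group means (see the methods
#' vignette); set them to 0 for an idealised homogeneous cohort.
#'
#' @param variance_ratio Median tremor variance as a multiple of background
#'   total variance; `>= 0`.
#' @param center_hz Tremor centre frequency, Hz, within the tremor band.
#' @param bandwidth_hz Full spectral width, Hz.
#' @param animal_sdlog Between-animal lognormal SD of tremor variance.
#' @param epoch_sdlog Within-animal between-epoch lognormal SD.
#' @param band [band_definition()]; tremor support must fit in its tremor band.
#' @return A `tremor_model` object.
#' @export
tremor_model <- function(variance_ratio = 2.24, center_hz = 12,
                         bandwidth_hz = 5, animal_sdlog = 0.5,
                         epoch_sdlog = 0.15, band = band_definition()) {
  stopifnot(inherits(band, "band_definition"))
  if (!is.finite(variance_ratio) || variance_ratio < 0)
    stop("variance_ratio must be >= 0", call. = FALSE)
  if (bandwidth_hz <= 0) stop("bandwidth_hz must be > 0", call. = FALSE)
  lo <- center_hz - bandwidth_hz / 2
  hi <- center_hz + bandwidth_hz / 2
  if (lo < band$tremor_lo || hi > band$tremor_hi)
    stop(sprintf("tremor support [%.3g, %.3g] must lie within [%g, %g] Hz",
                 lo, hi, band$tremor_lo, band$tremor_hi), call. = FALSE)
  if (animal_sdlog < 0 || epoch_sdlog < 0)
    stop("heterogeneity SDs must be >= 0", call. = FALSE)
  structure(list(variance_ratio = variance_ratio, center_hz = center_hz,
                 bandwidth_hz = bandwidth_hz, support = c(lo, hi),
                 animal_sdlog = animal_sdlog, epoch_sdlog = epoch_sdlog,
                 band = band),
            class = "tremor_model")
}

#' Drug pharmacodynamic model
#'
#' Dose maps to fractional suppression of tremor variance through a Hill/Emax
#' curve, `emax * dose^hill / (ed50^hill + dose^hill)`, applied only during
#' the drug's `active_epochs` (its clearance profile): alcohol is cleared
#' rapidly by mice so acts in E1 only; ganaxolone persists through E1-E4.
#' Suppression at dose 0 is 0 and is nondecreasing in dose.
#'
#' @param name Drug identifier. `drug_model("alcohol")` and
#'   `drug_model("ganaxolone")` return the study presets: alcohol doses
#'   0/0.40/0.50/0.575 g/kg with `emax 0.8, ed50 0.46 g/kg, hill 12`,
#'   active in E1; ganaxolone doses 0/3.5/7/10 mg/kg with
#'   `emax 0.8, ed50 5 mg/kg, hill 8`, active E1-E4. Hill steepness defaults
#'   make the lowest tested dose of each drug behave as a near-null, as
#'   observed.
#' @param dose_levels Ordered nonnegative dose values.
#' @param dose_units Unit string, e.g. `"g/kg"`.
#' @param emax Maximal fractional suppression, in `[0, 1]`.
#' @param ed50 Dose of half-maximal effect, same units as `dose_levels`.
#' @param hill Hill coefficient, `> 0`.
#' @param active_epochs Subset of `c("E1","E2","E3","E4")`.
#' @return A `drug_model` object.
#' @examples
#' drug_model("alcohol")
#' drug_model("custom", dose_levels = c(0, 1, 2), dose_units = "mg/kg",
#'            emax = 0.5, ed50 = 1, hill = 4, active_epochs = "E1")
#' @export
drug_model <- function(name, dose_levels = NULL, dose_units = NULL,
                       emax = NULL, ed50 = NULL, hill = NULL,
                       active_epochs = NULL) {
  presets <- list(
    alcohol = list(dose_levels = c(0, 0.40, 0.50, 0.575), dose_units = "g/kg",
                   emax = 0.8, ed50 = 0.46, hill = 12, active_epochs = "E1"),
    ganaxolone = list(dose_levels = c(0, 3.5, 7, 10), dose_units = "mg/kg",
                      emax = 0.8, ed50 = 5, hill = 8,
                      active_epochs = c("E1", "E2", "E3", "E4")))
  p <- presets[[name]]
  if (is.null(p)) {
    if (is.null(dose_levels) || is.null(emax) || is.null(ed50) ||
        is.null(hill) || is.null(active_epochs))
      stop("unknown drug preset '", name,
           "'; supply dose_levels, emax, ed50, hill and active_epochs",
           call. = FALSE)
    p <- list()
  }
  take <- function(x, d) if (is.null(x)) d else x
  dose_levels <- take(dose_levels, p$dose_levels)
  dose_units <- take(dose_units, p$dose_units)
  emax <- take(emax, p$emax); ed50 <- take(ed50, p$ed50)
  hill <- take(hill, p$hill)
  active_epochs <- take(active_epochs, p$active_epochs)
  if (any(dose_levels < 0)) stop("doses must be >= 0", call. = FALSE)
  if (is.unsorted(dose_levels, strictly = TRUE))
    stop("dose_levels must be strictly increasing", call. = FALSE)
  if (emax < 0 || emax > 1) stop("emax must be in [0, 1]", call. = FALSE)
  if (ed50 <= 0 || hill <= 0) stop("ed50 and hill must be > 0", call. = FALSE)
  if (!all(active_epochs %in% POST_EPOCHS))
    stop("active_epochs must be a subset of E1..E4", call. = FALSE)
  structure(list(name = name, dose_levels = dose_levels,
                 dose_units = dose_units, emax = emax, ed50 = ed50,
                 hill = hill, active_epochs = active_epochs),
            class = "drug_model")
}

#' Genotype of a simulated animal
#'
#' Knockout (KO) animals lacking the relevant extra-synaptic GABA-A receptor
#' subunit express normal baseline motion and normal harmaline tremor but do
#' not respond to the drug: all drug suppression is multiplied by 0. This is
#' the experiment's within-litter null contrast.
#'
#' @param label `"WT"` or `"KO"`.
#' @param drug_responsive Logical; defaults to `TRUE` for WT, `FALSE` for KO.
#'   A drug-responsive KO is invalid.
#' @return A `genotype` object.
#' @export
genotype <- function(label = c("WT", "KO"), drug_responsive = NULL) {
  label <- match.arg(label)
  if (is.null(drug_responsive)) drug_responsive <- label == "WT"
  if (label == "KO" && drug_responsive)
    stop("KO genotype cannot be drug_responsive", call. = FALSE)
  structure(list(label = label, drug_responsive = drug_responsive),
            class = "genotype")
}

#' Cohort design: genotypes x doses x group sizes x schedule
#'
#' Bundles everything needed to simulate one experiment arm: the drug model,
#' the genotypes run, per-(genotype, dose) group sizes, the epoch schedule,
#' the background and tremor models, and a master seed from which per-animal
#' seeds are derived deterministically.
#'
#' @param drug A [drug_model()].
#' @param genotypes List of [genotype()] objects (possibly empty).
#' @param group_sizes Either a single integer, a vector with one entry per
#'   dose (recycled across genotypes), or a matrix with one row per genotype
#'   and one column per dose. Every cell must be `>= 2`. Default 12,
#'   mirroring the study's 10-12 animals per cell.
#' @param schedule An [epoch_schedule()].
#' @param background A [background_model()].
#' @param tremor A [tremor_model()].
#' @param master_seed Integer master seed.
#' @return A `cohort_design` object.
#' @export
cohort_design <- function(drug, genotypes = list(genotype("WT")),
                          group_sizes = 12, schedule = epoch_schedule(),
                          background = background_model(),
                          tremor = tremor_model(), master_seed = 1L) {
  stopifnot(inherits(drug, "drug_model"), inherits(schedule, "epoch_schedule"),
            inherits(background, "background_model"),
            inherits(tremor, "tremor_model"))
  if (!is.list(genotypes) ||
      !all(vapply(genotypes, inherits, logical(1), "genotype")))
    stop("genotypes must be a list of genotype objects", call. = FALSE)
  ng <- length(genotypes); nd <- length(drug$dose_levels)
  if (is.matrix(group_sizes)) {
    if (!all(dim(group_sizes) == c(ng, nd)))
      stop("group_sizes matrix must be genotypes x doses", call. = FALSE)
    gs <- group_sizes
  } else {
    gs <- matrix(rep_len(as.integer(group_sizes), nd), nrow = max(ng, 1),
                 ncol = nd, byrow = TRUE)
  }
  if (ng > 0 && any(gs < 2))
    stop("every (genotype, dose) cell needs >= 2 animals", call. = FALSE)
  structure(list(drug = drug, genotypes = genotypes, group_sizes = gs,
                 schedule = schedule, background = background,
                 tremor = tremor, master_seed = as.integer(master_seed)),
            class = "cohort_design")
}

#' @export
print.drug_model <- function(x, ...) {
  cat(sprintf("<drug_model> %s: doses %s %s; Emax %.2f, ED50 %g, Hill %g; active %s\n",
              x$name, paste(x$dose_levels, collapse = "/"), x$dose_units,
              x$emax, x$ed50, x$hill, paste(x$active_epochs, collapse = ",")))
  invisible(x)
}
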