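#' Motion power percentage of one trace
#'
#' The tremor statistic: `100 * P(9-16 Hz) / P(0.25-32 Hz)` on the trace's
#' Welch PSD. Normalising tremor-band power by total motion power makes the
#' statistic insensitive to overall activity level and to amplitude scaling.
#'
#' @param trace A [motion_trace()] of at least `min_duration_s` seconds.
#' @param band A [band_definition()].
#' @param window_length_s,overlap_fraction,taper Passed to [estimate_psd()].
#' @param min_duration_s Minimum trace duration accepted (default 60 s).
#' @return An `mpp_record`: metadata plus `mpp` (percent, in `[0, 100]`),
#'   `tremor_band_power` and `total_band_power`.
#' @examples
#' tr <- simulate_background(120, 128, background_model(), seed = 1)
#' compute_mpp(tr)$mpp
#' @export
compute_mpp <- function(trace, band = band_definition(), window_length_s = 8,
                        overlap_fraction = 0.5, taper = "hann",
                        min_duration_s = 60) {
  stopifnot(inherits(trace, "motion_trace"))
  if (trace_duration(trace) < min_duration_s)
    stop(sprintf("trace too short: %.1f s < minimum %g s",
                 trace_duration(trace), min_duration_s), call. = FALSE)
  ps <- estimate_psd(trace, window_length_s, overlap_fraction, taper)
  tremor <- band_power(ps, band$tremor_lo, band$tremor_hi)
  total <- band_power(ps, band$total_lo, band$total_hi)
  if (total <= 0)
    stop("undefined statistic: total band power is zero (all-zero trace?)",
         call. = FALSE)
  structure(list(animal_id = trace$animal_id, genotype = trace$genotype,
                 drug = trace$drug, dose = trace$dose, epoch = trace$epoch,
                 mpp = 100 * tremor / total, tremor_band_power = tremor,
                 total_band_power = total),
            class = "mpp_record")
}

#' @export
print.mpp_record <- function(x, ...) {
  cat(sprintf("<mpp_record> %s %s epoch %s: MPP = %.2f%%\n",
              x$animal_id, x$genotype, x$epoch, x$mpp))
  invisible(x)
}

#' Tidy MPP table for a collection of traces
#'
#' One row per animal-epoch, ordered by (animal_id, canonical epoch order).
#' This is the unit of the downstream repeated-measures analysis.
#'
#' @param traces List of [motion_trace()] (e.g. `simulate_cohort(...)$traces`).
#' @param ... Passed to [compute_mpp()].
#' @return Data frame with columns `animal_id, genotype, drug, dose, epoch,
#'   mpp, tremor_band_power, total_band_power`.
#' @export
mpp_table <- function(traces, ...) {
  cols <- c("animal_id", "genotype", "drug", "dose", "epoch", "mpp",
            "tremor_band_power", "total_band_power")
  if (length(traces) == 0) {
    out <- data.frame(animal_id = character(), genotype = character(),
                      drug = character(), dose = numeric(),
                      epoch = character(), mpp = numeric(),
                      tremor_band_power = numeric(),
                      total_band_power = numeric(), stringsAsFactors = FALSE)
    return(out[cols])
  }
  recs <- lapply(traces, compute_mpp, ...)
  field <- function(name, cast) cast(unlist(lapply(recs, `[[`, name)))
  out <- data.frame(animal_id = field("animal_id", as.character),
                    genotype = field("genotype", as.character),
                    drug = field("drug", as.character),
                    dose = field("dose", as.numeric),
                    epoch = field("epoch", as.character),
                    mpp = field("mpp", as.numeric),
                    tremor_band_power = field("tremor_band_power", as.numeric),
                    total_band_power = field("total_band_power", as.numeric),
                    stringsAsFactors = FALSE)
  if (anyDuplicated(out[c("animal_id", "epoch")]))
    stop("duplicate (animal, epoch) rows in trace collection", call. = FALSE)
  ord <- order(out$animal_id, match(out$epoch, EPOCH_LEVELS))
  out <- out[ord, cols]
  rownames(out) <- NULL
  out
}
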