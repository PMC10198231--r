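#' Experiment configuration
#'
#' A serializable description of one experiment arm (one drug, one mouse
#' line, both genotypes): everything [run_experiment()] needs. All fields are
#' plain scalars/vectors so a config round-trips exactly through JSON
#' ([write_config()] / [read_config()]).
#'
#' @param drug_name Drug identifier (preset or custom).
#' @param line_name Mouse line label (e.g. `"delta"`, `"alpha6"`); metadata.
#' @param genotypes Character vector, subset of `c("WT", "KO")`.
#' @param group_sizes Named list: one integer vector per genotype, one entry
#'   per dose.
#' @param dose_levels,dose_units,emax,ed50,hill,active_epochs Drug model
#'   fields; defaults from [drug_model()] presets when `drug_name` is one.
#' @param epoch_labels,duration_s,gap_before_s Schedule fields.
#' @param total_variance,in_band_fraction,animal_logit_sd Background model.
#' @param variance_ratio,center_hz,bandwidth_hz,animal_sdlog,epoch_sdlog
#'   Tremor model.
#' @param sample_rate_hz Sampling rate (128 Hz hardware default).
#' @param window_length_s,overlap_fraction,taper Welch estimator settings.
#' @param alpha Significance level.
#' @param master_seed Integer master seed.
#' @param retain_traces Keep simulated traces on disk? Default `FALSE` (90
#'   animals x 7 x 15 min x 128 Hz is large relative to its value).
#' @param hardware_filter Emulate the 1-70 Hz amplifier passband.
#' @return An `experiment_config`.
#' @export
experiment_config <- function(drug_name = "alcohol", line_name = "delta",
                              genotypes = c("WT", "KO"),
                              group_sizes = NULL,
                              dose_levels = NULL, dose_units = NULL,
                              emax = NULL, ed50 = NULL, hill = NULL,
                              active_epochs = NULL,
                              epoch_labels = EPOCH_LEVELS,
                              duration_s = 900, gap_before_s = NULL,
                              total_variance = 1, in_band_fraction = 0.32,
                              animal_logit_sd = 0.25,
                              variance_ratio = 2.24, center_hz = 12,
                              bandwidth_hz = 5, animal_sdlog = 0.5,
                              epoch_sdlog = 0.15,
                              sample_rate_hz = 128,
                              window_length_s = 8, overlap_fraction = 0.5,
                              taper = "hann", alpha = 0.05,
                              master_seed = 1L, retain_traces = FALSE,
                              hardware_filter = FALSE) {
  drug <- drug_model(drug_name, dose_levels, dose_units, emax, ed50, hill,
                     active_epochs)
  genotypes <- as.character(genotypes)
  if (!all(genotypes %in% c("WT", "KO")))
    stop("genotypes must be a subset of WT, KO", call. = FALSE)
  nd <- length(drug$dose_levels)
  if (is.null(group_sizes))
    group_sizes <- setNames(rep(list(rep(12L, nd)), length(genotypes)),
                            genotypes)
  if (!all(genotypes %in% names(group_sizes)))
    stop("group_sizes needs one vector per genotype", call. = FALSE)
  group_sizes <- lapply(group_sizes[genotypes],
                        function(v) as.integer(rep_len(v, nd)))
  schedule <- epoch_schedule(epoch_labels, duration_s, gap_before_s)
  cfg <- list(drug_name = drug$name,
              line_name = as.character(line_name),
              genotypes = genotypes, group_sizes = group_sizes,
              dose_levels = as.numeric(drug$dose_levels),
              dose_units = drug$dose_units,
              emax = as.numeric(drug$emax), ed50 = as.numeric(drug$ed50),
              hill = as.numeric(drug$hill),
              active_epochs = as.character(drug$active_epochs),
              epoch_labels = as.character(schedule$label),
              duration_s = as.numeric(schedule$duration_s),
              gap_before_s = as.numeric(schedule$gap_before_s),
              total_variance = as.numeric(total_variance),
              in_band_fraction = as.numeric(in_band_fraction),
              animal_logit_sd = as.numeric(animal_logit_sd),
              variance_ratio = as.numeric(variance_ratio),
              center_hz = as.numeric(center_hz),
              bandwidth_hz = as.numeric(bandwidth_hz),
              animal_sdlog = as.numeric(animal_sdlog),
              epoch_sdlog = as.numeric(epoch_sdlog),
              sample_rate_hz = as.numeric(sample_rate_hz),
              window_length_s = as.numeric(window_length_s),
              overlap_fraction = as.numeric(overlap_fraction),
              taper = as.character(taper), alpha = as.numeric(alpha),
              master_seed = as.integer(master_seed),
              retain_traces = isTRUE(retain_traces),
              hardware_filter = isTRUE(hardware_filter))
  structure(cfg, class = "experiment_config")
}

#' @export
print.experiment_config <- function(x, ...) {
  cat(sprintf("<experiment_config> %s / %s line: %s; doses %s %s; seed %d\n",
              x$drug_name, x$line_name, paste(x$genotypes, collapse = "+"),
              paste(x$dose_levels, collapse = "/"), x$dose_units,
              x$master_seed))
  invisible(x)
}

#' @rdname experiment_config
#' @param config An `experiment_config`.
#' @param path JSON file path.
#' @export
write_config <- function(config, path) {
  stopifnot(inherits(config, "experiment_config"))
  jsonlite::write_json(unclass(config), path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname experiment_config
#' @export
read_config <- function(path) {
  raw <- jsonlite::fromJSON(path, simplifyVector = TRUE)
  experiment_config(
    drug_name = raw$drug_name, line_name = raw$line_name,
    genotypes = raw$genotypes, group_sizes = raw$group_sizes,
    dose_levels = raw$dose_levels, dose_units = raw$dose_units,
    emax = raw$emax, ed50 = raw$ed50, hill = raw$hill,
    active_epochs = raw$active_epochs, epoch_labels = raw$epoch_labels,
    duration_s = raw$duration_s, gap_before_s = raw$gap_before_s,
    total_variance = raw$total_variance,
    in_band_fraction = raw$in_band_fraction,
    animal_logit_sd = raw$animal_logit_sd,
    variance_ratio = raw$variance_ratio, center_hz = raw$center_hz,
    bandwidth_hz = raw$bandwidth_hz, animal_sdlog = raw$animal_sdlog,
    epoch_sdlog = raw$epoch_sdlog, sample_rate_hz = raw$sample_rate_hz,
    window_length_s = raw$window_length_s,
    overlap_fraction = raw$overlap_fraction, taper = raw$taper,
    alpha = raw$alpha, master_seed = raw$master_seed,
    retain_traces = raw$retain_traces, hardware_filter = raw$hardware_filter)
}

config_to_design <- function(config, master_seed = NULL) {
  band <- band_definition()
  gs <- do.call(rbind, config$group_sizes[config$genotypes])
  cohort_design(
    drug = drug_model(config$drug_name, config$dose_levels,
                      config$dose_units, config$emax, config$ed50,
                      config$hill, config$active_epochs),
    genotypes = lapply(config$genotypes, genotype),
    group_sizes = gs,
    schedule = epoch_schedule(config$epoch_labels, config$duration_s,
                              config$gap_before_s),
    background = background_model(config$total_variance,
                                  config$in_band_fraction,
                                  config$animal_logit_sd, band),
    tremor = tremor_model(config$variance_ratio, config$center_hz,
                          config$bandwidth_hz, config$animal_sdlog,
                          config$epoch_sdlog, band),
    master_seed = master_seed %||% config$master_seed)
}

#' Study-design presets
#'
#' Returns the [experiment_config()] matching one of the study's four
#' experiment arms, with the published group sizes:
#' \tabular{lll}{
#'   drug \tab line \tab n per dose (WT; KO) \cr
#'   alcohol \tab delta \tab 11,11,12,11; 11,11,12,11 \cr
#'   alcohol \tab alpha6 \tab 12,11,12,12; 12,12,12,12 \cr
#'   ganaxolone \tab delta \tab 11,11,10,11; 11,11,11,11 \cr
#'   ganaxolone \tab alpha6 \tab 12,12,12,12; 12,12,12,12 \cr
#' }
#'
#' @param drug_name `"alcohol"` or `"ganaxolone"`.
#' @param line_name `"delta"` or `"alpha6"`.
#' @param ... Overrides passed on to [experiment_config()].
#' @return An `experiment_config`.
#' @export
make_paper_defaults <- function(drug_name, line_name, ...) {
  sizes <- list(
    alcohol.delta = list(WT = c(11L, 11L, 12L, 11L), KO = c(11L, 11L, 12L, 11L)),
    alcohol.alpha6 = list(WT = c(12L, 11L, 12L, 12L), KO = c(12L, 12L, 12L, 12L)),
    ganaxolone.delta = list(WT = c(11L, 11L, 10L, 11L), KO = c(11L, 11L, 11L, 11L)),
    ganaxolone.alpha6 = list(WT = c(12L, 12L, 12L, 12L), KO = c(12L, 12L, 12L, 12L)))
  key <- paste(drug_name, line_name, sep = ".")
  if (!key %in% names(sizes))
    stop("unknown drug/line combination: ", key, call. = FALSE)
  experiment_config(drug_name = drug_name, line_name = line_name,
                    group_sizes = sizes[[key]], ...)
}

#' Analyze an MPP table
#'
#' The inference half of the pipeline, usable on its own (e.g. to regenerate
#' a report from a retained `mpp.csv` without re-simulating). Fits the
#' repeated-measures model per genotype, runs the protected Fisher-LSD
#' dose-versus-vehicle comparisons at every post-treatment epoch, and checks
#' residual normality.
#'
#' @param mpp MPP table (as from [mpp_table()] or read from CSV); must carry
#'   a `genotype` column.
#' @param alpha Significance level.
#' @param response Response column, default `"mpp"`.
#' @return Named list (one element per genotype) of lists with `fit`,
#'   `comparisons`, `summary`, `normality`, `curves`.
#' @export
analyze_mpp <- function(mpp, alpha = 0.05, response = "mpp") {
  stopifnot(is.data.frame(mpp), "genotype" %in% names(mpp))
  genos <- intersect(c("WT", "KO"), unique(mpp$genotype))
  if (length(genos) == 0) genos <- unique(mpp$genotype)
  out <- lapply(genos, function(g) {
    sub <- mpp[mpp$genotype == g, , drop = FALSE]
    fit <- fit_rm_anova(sub, response = response, alpha = alpha)
    vehicle <- min(fit$dose_levels)
    cells <- expand.grid(epoch = intersect(POST_EPOCHS, fit$epochs),
                         dose = setdiff(fit$dose_levels, vehicle),
                         stringsAsFactors = FALSE)
    comparisons <- lapply(seq_len(nrow(cells)), function(i)
      lsd_compare(fit, cells$epoch[i], cells$dose[i], vehicle, alpha))
    smry <- summarize_experiment(fit, comparisons)
    normality <- if (fit$degenerate) NULL else check_residual_normality(fit)
    curves <- cbind(genotype = g, fit$means, stringsAsFactors = FALSE)
    list(fit = fit, comparisons = comparisons, summary = smry,
         normality = normality, curves = curves)
  })
  names(out) <- genos
  out
}

#' Run one experiment end to end
#'
#' simulate -> quantify -> analyze -> report. Per-animal seeds derive from
#' the config's master seed, so rerunning the same config reproduces every
#' number bit-identically.
#'
#' @param config An [experiment_config()].
#' @param out_dir Optional output directory; when given, writes
#'   `config.json`, `manifest.csv`, `mpp.csv`, `results.csv`, `curves.csv`,
#'   `normality.csv`, `model_summary.txt` (and `traces/` if
#'   `config$retain_traces`).
#' @param master_seed Optional override of the config's master seed.
#' @return An `experiment_report`: the analysis per genotype plus the MPP
#'   table, manifest, combined results table and a provenance block.
#' @export
run_experiment <- function(config, out_dir = NULL, master_seed = NULL) {
  stopifnot(inherits(config, "experiment_config"))
  design <- config_to_design(config, master_seed)
  cohort <- simulate_cohort(design, hardware_filter = config$hardware_filter)
  mpp <- mpp_table(cohort$traces,
                   window_length_s = config$window_length_s,
                   overlap_fraction = config$overlap_fraction,
                   taper = config$taper)
  analysis <- analyze_mpp(mpp, alpha = config$alpha)
  results <- do.call(rbind, lapply(analysis, `[[`, "summary"))
  rownames(results) <- NULL
  curves <- do.call(rbind, lapply(analysis, `[[`, "curves"))
  rownames(curves) <- NULL

  cfg_file <- file.path(tempdir(), "tremorMPP-config.json")
  write_config(config, cfg_file)
  provenance <- list(config_hash = unname(md5sum(cfg_file)),
                     master_seed = master_seed %||% config$master_seed,
                     package_version = as.character(packageVersion("tremorMPP")),
                     r_version = R.version.string,
                     timestamp = format(Sys.time(), tz = "UTC"))

  report <- structure(list(config = config, manifest = cohort$manifest,
                           mpp = mpp, analysis = analysis, results = results,
                           curves = curves, provenance = provenance),
                      class = "experiment_report")
  if (!is.null(out_dir)) write_report(report, out_dir,
                                      cohort = if (config$retain_traces) cohort)
  report
}

write_report <- function(report, out_dir, cohort = NULL) {
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  write_config(report$config, file.path(out_dir, "config.json"))
  write.csv(report$manifest, file.path(out_dir, "manifest.csv"),
            row.names = FALSE)
  write.csv(report$mpp, file.path(out_dir, "mpp.csv"), row.names = FALSE)
  write.csv(report$results, file.path(out_dir, "results.csv"),
            row.names = FALSE)
  write.csv(report$curves, file.path(out_dir, "curves.csv"),
            row.names = FALSE)
  norm <- do.call(rbind, lapply(names(report$analysis), function(g) {
    nr <- report$analysis[[g]]$normality
    if (is.null(nr)) return(NULL)
    data.frame(genotype = g, W = nr$W, p_value = nr$p_value)
  }))
  if (!is.null(norm))
    write.csv(norm, file.path(out_dir, "normality.csv"), row.names = FALSE)
  qq <- do.call(rbind, lapply(names(report$analysis), function(g) {
    nr <- report$analysis[[g]]$normality
    if (is.null(nr)) return(NULL)
    cbind(genotype = g, nr$qq)
  }))
  if (!is.null(qq))
    write.csv(qq, file.path(out_dir, "qq_coordinates.csv"), row.names = FALSE)
  lines <- unlist(lapply(names(report$analysis), function(g)
    c(format_fit_summary(report$analysis[[g]]$fit,
                         report$analysis[[g]]$normality), "")))
  lines <- c(lines,
             sprintf("provenance: seed %d, config %s, %s, tremorMPP %s",
                     report$provenance$master_seed,
                     report$provenance$config_hash,
                     report$provenance$r_version,
                     report$provenance$package_version))
  writeLines(lines, file.path(out_dir, "model_summary.txt"))
  if (!is.null(cohort)) write_cohort(cohort, file.path(out_dir, "traces"))
  invisible(out_dir)
}

#' @export
print.experiment_report <- function(x, ...) {
  cat(sprintf("<experiment_report> %s / %s: %d animals, %d MPP records\n",
              x$config$drug_name, x$config$line_name, nrow(x$manifest),
              nrow(x$mpp)))
  sig <- x$results[x$results$significant, , drop = FALSE]
  if (nrow(sig) == 0) cat("  no significant dose comparisons\n")
  else print(sig[c("genotype", "epoch", "dose", "diff_vs_vehicle", "p", "stars")],
             row.names = FALSE, digits = 4)
  invisible(x)
}
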