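#' Write / read motion traces as delimited text
#'
#' One file per animal-epoch: a two-column tab-delimited table
#' (`time_s`, `force`) plus a sidecar `.meta` key-value file carrying
#' `animal_id, genotype, drug, dose, epoch, sample_rate_hz, seed`.
#'
#' @param trace A [motion_trace()].
#' @param dir Output directory (created if needed).
#' @return `write_trace` invisibly returns the trace file path; `read_trace`
#'   returns a [motion_trace()]; `read_trace_dir` a named list of traces.
#' @export
write_trace <- function(trace, dir) {
  stopifnot(inherits(trace, "motion_trace"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  stem <- file.path(dir, paste0(trace$animal_id, "_", trace$epoch))
  n <- length(trace$samples)
  df <- data.frame(time_s = (seq_len(n) - 1) / trace$sample_rate_hz,
                   force = trace$samples)
  write.table(df, paste0(stem, ".tsv"), sep = "\t", row.names = FALSE,
              quote = FALSE)
  meta <- c(animal_id = trace$animal_id, genotype = trace$genotype,
            drug = trace$drug, dose = format(trace$dose, digits = 15),
            epoch = trace$epoch,
            sample_rate_hz = format(trace$sample_rate_hz, digits = 15),
            seed = format(trace$seed))
  writeLines(paste(names(meta), meta, sep = "\t"), paste0(stem, ".meta"))
  invisible(paste0(stem, ".tsv"))
}

#' @rdname write_trace
#' @param path Path to a trace `.tsv` file (sidecar `.meta` expected next to it).
#' @export
read_trace <- function(path) {
  df <- read.table(path, header = TRUE, sep = "\t")
  if (!all(c("time_s", "force") %in% names(df)))
    stop("trace file must have columns time_s, force: ", path, call. = FALSE)
  meta_path <- sub("\\.tsv$", ".meta", path)
  meta <- list(sample_rate_hz = NA, animal_id = NA, genotype = NA, drug = NA,
               dose = NA, epoch = NA, seed = NA)
  if (file.exists(meta_path)) {
    kv <- read.table(meta_path, sep = "\t", header = FALSE,
                     col.names = c("key", "value"),
                     colClasses = "character")
    meta[kv$key] <- kv$value
  }
  fs <- suppressWarnings(as.numeric(meta$sample_rate_hz))
  if (!is.finite(fs)) {
    dt <- diff(df$time_s[1:2])
    fs <- 1 / dt
  }
  motion_trace(df$force, fs, animal_id = as.character(meta$animal_id),
               genotype = as.character(meta$genotype),
               drug = as.character(meta$drug),
               dose = suppressWarnings(as.numeric(meta$dose)),
               epoch = as.character(meta$epoch),
               seed = suppressWarnings(as.integer(meta$seed)))
}

#' @rdname write_trace
#' @export
read_trace_dir <- function(dir) {
  files <- sort(list.files(dir, pattern = "\\.tsv$", full.names = TRUE))
  traces <- lapply(files, read_trace)
  names(traces) <- vapply(traces, function(tr) paste(tr$animal_id, tr$epoch,
                                                     sep = "."), character(1))
  traces
}

#' Write a cohort's traces and manifest to disk
#'
#' @param cohort A `tremor_cohort` from [simulate_cohort()].
#' @param dir Output directory.
#' @return Invisibly, the manifest CSV path.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "tremor_cohort"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  for (tr in cohort$traces) write_trace(tr, dir)
  path <- file.path(dir, "manifest.csv")
  write.csv(cohort$manifest, path, row.names = FALSE)
  invisible(path)
}
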