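EPOCH_LEVELS <- c("B", "H1", "H2", "E1", "E2", "E3", "E4")
POST_EPOCHS <- c("E1", "E2", "E3", "E4")

#' Recording epoch schedule
#'
#' The experiment records seven 15-minute epochs per animal: pre-harmaline
#' baseline (B), two harmaline pre-treatment epochs (H1, H2) separated by a
#' 5-minute home-cage rest, then -- 10 minutes after drug or vehicle
#' injection -- four post-treatment epochs (E1-E4) with 5-minute rests.
#' `gap_before_s` is unrecorded time preceding each epoch (the B gap is the
#' acclimation/harmaline-onset interval and defaults to 0 here).
#'
#' @param labels Epoch labels, a subset of `c("B","H1","H2","E1","E2","E3","E4")`
#'   in that canonical order.
#' @param duration_s Epoch durations in seconds (recycled). Default 900.
#' @param gap_before_s Unrecorded seconds before each epoch (recycled over the
#'   non-default case); defaults follow the published schedule: 300 s rests,
#'   600 s between injection and E1, 0 before B.
#' @return An `epoch_schedule` data frame with columns `label`, `duration_s`,
#'   `gap_before_s`.
#' @examples
#' epoch_schedule()
#' epoch_schedule(c("B", "H1", "E1"), duration_s = 300)
#' @export
epoch_schedule <- function(labels = EPOCH_LEVELS, duration_s = 900,
                           gap_before_s = NULL) {
  labels <- as.character(labels)
  if (anyDuplicated(labels)) stop("epoch labels must be unique", call. = FALSE)
  if (!all(labels %in% EPOCH_LEVELS))
    stop("unknown epoch label(s): ",
         paste(setdiff(labels, EPOCH_LEVELS), collapse = ", "), call. = FALSE)
  if (!identical(labels, intersect(EPOCH_LEVELS, labels)))
    stop("epoch labels must appear in canonical order B, H1, H2, E1..E4",
         call. = FALSE)
  duration_s <- rep_len(as.numeric(duration_s), length(labels))
  if (any(!is.finite(duration_s)) || any(duration_s <= 0))
    stop("all epoch durations must be positive", call. = FALSE)
  if (is.null(gap_before_s)) {
    gap_before_s <- ifelse(labels == "B", 0,
                    ifelse(labels == "E1", 600, 300))
  } else {
    gap_before_s <- rep_len(as.numeric(gap_before_s), length(labels))
  }
  if (any(gap_before_s < 0)) stop("gaps must be nonnegative", call. = FALSE)
  structure(data.frame(label = labels, duration_s = duration_s,
                       gap_before_s = gap_before_s,
                       stringsAsFactors = FALSE),
            class = c("epoch_schedule", "data.frame"))
}
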