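#' Screen candidate squeals by the inclusion rules
#'
#' Applies the study's squeal inclusion rules to a metadata table:
#' a squeal is analyzed iff
#' \enumerate{
#'   \item its duration is at least `min_dur_s` seconds,
#'   \item its mean background-noise rating (per-rater scores 0-2) does
#'     not exceed `max_mean_rating` — a mean of exactly 1.00 is included,
#'     only means strictly above the threshold are excluded, and
#'   \item it carries no audible-artifact flag.
#' }
#' Rules are evaluated in that order and each excluded squeal is labeled
#' with its first failing rule. With three integer raters, means are
#' multiples of 1/3; the comparison against the threshold is done on the
#' rating sum scaled by the rater count (integers vs. `threshold * n`) with
#' a half-machine-epsilon guard, so a mean of exactly 1.00 never trips the
#' threshold through floating-point rounding.
#'
#' @param records A data frame with one row per candidate squeal and
#'   columns `duration` (seconds), `ratings` (a list-column of per-rater
#'   integer scores in 0-2, or a single numeric column of mean ratings)
#'   and `artifact` (logical). Other columns pass through.
#' @param min_dur_s Minimum duration in seconds (default 0.3).
#' @param max_mean_rating Maximum admissible mean noise rating
#'   (default 1.00).
#' @return The input tibble plus columns `included` (logical),
#'   `exclusion_reason` (`NA`, `"duration"`, `"noise_rating"` or
#'   `"artifact"`) and `mean_rating`.
#' @export
#' @examples
#' records <- tibble::tibble(
#'   clip_id = c("a", "b", "c"),
#'   duration = c(0.5, 0.25, 0.5),
#'   ratings = list(c(1, 1, 1), c(0, 0, 0), c(2, 1, 1)),
#'   artifact = FALSE
#' )
#' screen_squeals(records)
screen_squeals <- function(records, min_dur_s = 0.3, max_mean_rating = 1.00) {
  stopifnot(is.data.frame(records))
  if (nrow(records) == 0L) {
    stop("`records` must contain at least one squeal", call. = FALSE)
  }
  req <- c("duration", "ratings", "artifact")
  missing_cols <- setdiff(req, names(records))
  if (length(missing_cols) > 0L) {
    stop("`records` is missing columns: ",
      paste(missing_cols, collapse = ", "),
      call. = FALSE
    )
  }
  records <- tibble::as_tibble(records)
  if (any(records$duration <= 0)) {
    stop("all durations must be positive", call. = FALSE)
  }

  rating_list <- if (is.list(records$ratings)) {
    records$ratings
  } else {
    as.list(records$ratings)
  }
  ok <- vapply(rating_list, function(r) {
    length(r) >= 1L && all(r %in% c(0, 1, 2))
  }, logical(1L))
  if (!all(ok)) {
    stop("every rating must be in {0, 1, 2} and nonempty", call. = FALSE)
  }

  # exact comparison on the rating sum: mean > thr  <=>  sum > thr * n
  noisy <- vapply(rating_list, function(r) {
    sum(r) > max_mean_rating * length(r) + .Machine$double.eps^0.5
  }, logical(1L))
  mean_rating <- vapply(rating_list, mean, numeric(1L))

  too_short <- records$duration < min_dur_s
  artifact <- as.logical(records$artifact)

  reason <- rep(NA_character_, nrow(records))
  reason[artifact] <- "artifact"
  reason[noisy] <- "noise_rating" # earlier rules overwrite later ones
  reason[too_short] <- "duration"

  dplyr::mutate(records,
    mean_rating = mean_rating,
    included = is.na(reason),
    exclusion_reason = reason
  )
}
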