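#' Run the full squeal analysis pipeline on a cohort
#'
#' Wires the stages end to end in the fixed analysis order: screen the
#' metadata, extract the fourteen aperiodic parameters from the included
#' squeals, and run the per-animal one-sided Wilcoxon tests under BY FDR
#' control. Each intermediate table is returned so stages can be inspected
#' or checkpointed to CSV.
#'
#' @param cohort A cohort tibble with a list-column `clip` and the
#'   metadata columns used by [screen_squeals()] (`duration`, `ratings`,
#'   `artifact`) plus `pig_id` and `phase`.
#' @param plan A [window_plan()].
#' @param hypotheses A hypothesis table (see [default_hypotheses()]).
#' @param alpha FDR level.
#' @param include_cpp Also compute CPP (descriptive only).
#' @return A list with elements `screening` (the screened metadata),
#'   `features` (parameter table of included squeals) and `comparison`
#'   (a `squeal_comparison`).
#' @export
#' @examples
#' \donttest{
#' cohort <- generate_cohort(
#'   squeal_model(duration_s = 0.35),
#'   squeal_model(rolloff_cutoff = 2000, duration_s = 0.35),
#'   n_pre = 8, n_post = 8, seed = 11
#' )
#' out <- run_squeal_pipeline(cohort)
#' glance(out$comparison)
#' }
run_squeal_pipeline <- function(cohort, plan = window_plan(),
                                hypotheses = default_hypotheses(),
                                alpha = 0.05, include_cpp = FALSE) {
  screening <- screen_squeals(cohort)
  included <- screening[screening$included, , drop = FALSE]
  if (nrow(included) == 0L) {
    stop("no squeals pass screening", call. = FALSE)
  }
  features <- extract_features(included, plan = plan,
    include_cpp = include_cpp
  )
  comparison <- compare_phases(features, hypotheses = hypotheses,
    alpha = alpha
  )
  list(
    screening = dplyr::select(screening, -dplyr::any_of("clip")),
    features = features,
    comparison = comparison
  )
}

#' Write a feature or screening table to CSV
#'
#' List-columns (per-rater ratings, clips) are flattened or dropped:
#' ratings become a `;`-separated string, clips are omitted. The layout is
#' one row per squeal — the interchange format between pipeline stages.
#'
#' @param x A tibble from [extract_features()], [screen_squeals()] or
#'   [tidy()] of a comparison.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_squeal_csv <- function(x, path) {
  stopifnot(is.data.frame(x))
  x <- tibble::as_tibble(x)
  if ("clip" %in% names(x)) x$clip <- NULL
  if ("ratings" %in% names(x) && is.list(x$ratings)) {
    x$ratings <- vapply(x$ratings, paste, character(1L), collapse = ";")
  }
  utils::write.csv(x, path, row.names = FALSE)
  invisible(path)
}

#' Read a squeal metadata CSV
#'
#' Inverse of [write_squeal_csv()] for metadata tables: the `ratings`
#' column, if present as `;`-separated strings, is re-expanded into a
#' list-column of numeric per-rater scores.
#'
#' @param path CSV path.
#' @return A tibble.
#' @export
read_squeal_csv <- function(path) {
  x <- tibble::as_tibble(utils::read.csv(path, stringsAsFactors = FALSE))
  if ("ratings" %in% names(x) && is.character(x$ratings)) {
    x$ratings <- lapply(strsplit(x$ratings, ";", fixed = TRUE), as.numeric)
  }
  x
}

#' Simulate a squeal dataset on disk
#'
#' Writes each generated clip as a 16-bit WAV file plus a metadata CSV, so
#' the downstream stages can be exercised from files exactly as they would
#' be with real recordings.
#'
#' @inheritParams generate_cohort
#' @param dir Output directory (created if missing).
#' @return The metadata tibble (with a `file` column), invisibly.
#' @export
simulate_dataset <- function(pre_model, post_model, n_pre = 20L,
                             n_post = 20L, pig_id = "pig1",
                             jitter = cohort_jitter(), sample_rate = 44100,
                             seed = NULL, dir = ".") {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  cohort <- generate_cohort(pre_model, post_model,
    n_pre = n_pre, n_post = n_post, pig_id = pig_id,
    jitter = jitter, sample_rate = sample_rate, seed = seed
  )
  cohort$file <- file.path(dir, paste0(cohort$clip_id, ".wav"))
  purrr::walk2(cohort$clip, cohort$file, write_wav)
  meta <- dplyr::select(cohort, -"clip")
  write_squeal_csv(meta, file.path(dir, "metadata.csv"))
  invisible(meta)
}
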