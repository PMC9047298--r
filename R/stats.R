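#' One-sided Wilcoxon rank-sum p-value for a pre/post contrast
#'
#' Tests whether the post-phase values are shifted in the hypothesized
#' direction relative to the pre-phase values: `direction = "increase"`
#' tests H1 "post > pre", `"decrease"` tests H1 "post < pre". The test is
#' exact (full enumeration of the rank-sum distribution) when the combined
#' sample size is at most 20 and there are no ties; otherwise the normal
#' approximation with tie and continuity corrections is used.
#'
#' @param x_pre,y_post Numeric samples for the two phases (nonempty).
#' @param direction Expected post-surgery change: `"decrease"` or
#'   `"increase"`.
#' @param exact_max_n Combined sample size at or below which the exact
#'   distribution is used (ties permitting).
#' @return The one-sided p-value.
#' @export
#' @examples
#' wilcoxon_one_sided(c(1, 2), c(3, 4), "increase") # 1/6
wilcoxon_one_sided <- function(x_pre, y_post,
                               direction = c("decrease", "increase"),
                               exact_max_n = 20L) {
  direction <- match.arg(direction)
  if (length(x_pre) < 1L || length(y_post) < 1L) {
    stop("both samples must be nonempty", call. = FALSE)
  }
  if (anyNA(x_pre) || anyNA(y_post)) stop("samples contain NA", call. = FALSE)
  all_vals <- c(x_pre, y_post)
  if (length(unique(all_vals)) == 1L) {
    warning("degenerate data: all values identical across both groups; p = 1")
    return(1)
  }
  has_ties <- anyDuplicated(all_vals) > 0L
  use_exact <- (length(all_vals) <= exact_max_n) && !has_ties
  alt <- if (direction == "increase") "greater" else "less"
  res <- suppressWarnings(stats::wilcox.test(
    y_post, x_pre,
    alternative = alt, exact = use_exact, correct = TRUE
  ))
  unname(res$p.value)
}

#' Benjamini-Yekutieli FDR correction
#'
#' Step-up false-discovery-rate control valid under arbitrary dependence
#' between the tests: the rank-`i` threshold is `i * alpha / (m * c(m))`
#' with the harmonic correction `c(m) = sum(1/i, i = 1..m)`; equivalently,
#' adjusted p-values are compared against `alpha`. More conservative than
#' Benjamini-Hochberg on every p-vector.
#'
#' @param p_values Numeric vector of raw p-values in `[0, 1]`.
#' @param alpha Target FDR level (default 0.05).
#' @return A tibble with columns `p_raw`, `p_adj` (BY-adjusted, capped at
#'   1) and `rejected`, in the input order.
#' @export
#' @examples
#' by_fdr(c(0.001, 0.02, 0.9))
by_fdr <- function(p_values, alpha = 0.05) {
  if (length(p_values) == 0L) stop("empty p-value vector", call. = FALSE)
  if (anyNA(p_values) || any(p_values < 0 | p_values > 1)) {
    stop("p-values must lie in [0, 1]", call. = FALSE)
  }
  p_adj <- stats::p.adjust(p_values, method = "BY")
  tibble::tibble(
    p_raw = p_values,
    p_adj = p_adj,
    rejected = p_adj <= alpha
  )
}

#' Default hypothesis directions for the aperiodic parameters
#'
#' The expected direction of each parameter's post-surgery change, encoding
#' the physical picture of the impaired voice: reduced high-frequency
#' energy lowers all frequency-location parameters (PF, the Q50 family,
#' Q50W, Q25); spectral flatness and flux increase as the voice becomes
#' noisier and less stable in time; RMSI increases as the waveform loses
#' dominant peaks; duration and HNR are expected to decrease. The direction
#' for `Q50_n` (an inner-window index, weakly informative) and for `SF_Q50`
#' (flatness up but its Q50 denominator down) is genuinely ambiguous;
#' the defaults follow `Q50_n` down with the frequency family and `SF_Q50`
#' up with its flatness numerator. Override any entry by passing an edited
#' copy of this table to [compare_phases()].
#'
#' @return A tibble with columns `parameter` and `direction`
#'   (`"decrease"`/`"increase"`), one row per aperiodic parameter.
#' @export
default_hypotheses <- function() {
  decrease <- c(
    "PF", "Q50", "Q50_2", "Q50_10", "Q50_min", "Q50W", "Q25",
    "Dur", "Q50_n", "HNR"
  )
  increase <- c("SF", "SF_Q50", "Flux", "RMSI")
  tibble::tibble(
    parameter = c(decrease, increase),
    direction = c(
      rep("decrease", length(decrease)),
      rep("increase", length(increase))
    )
  )[match(aperiodic_parameters(), c(decrease, increase)), ]
}

#' Per-animal pre/post comparison of all aperiodic parameters
#'
#' For each animal independently (animals are never pooled or compared
#' with each other): runs the one-sided Wilcoxon rank-sum test of every
#' parameter in `hypotheses` against its expected direction, applies
#' Benjamini-Yekutieli FDR control at `alpha` within that animal, and
#' assigns the two significance tiers used in reporting (`*` for adjusted
#' p <= 0.05, `***` for adjusted p <= 0.001).
#'
#' @param features A feature table from [extract_features()]: one row per
#'   squeal with columns `pig_id`, `phase` (`"pre"`/`"post"`) and the
#'   parameter columns.
#' @param hypotheses A hypothesis table like [default_hypotheses()].
#' @param alpha FDR level (default 0.05).
#' @return A `squeal_comparison` object; use [generics::tidy()] for the
#'   per-test tibble (pig, parameter, sample sizes, direction, raw and
#'   adjusted p, significance) and [generics::glance()] for a one-row
#'   summary.
#' @export
#' @examples
#' \donttest{
#' cohort <- generate_cohort(
#'   squeal_model(duration_s = 0.35),
#'   squeal_model(rolloff_cutoff = 2000, duration_s = 0.35),
#'   n_pre = 8, n_post = 8, seed = 7
#' )
#' feats <- extract_features(cohort)
#' cmp <- compare_phases(feats)
#' tidy(cmp)
#' }
compare_phases <- function(features, hypotheses = default_hypotheses(),
                           alpha = 0.05) {
  stopifnot(is.data.frame(features), is.data.frame(hypotheses))
  req <- c("pig_id", "phase")
  if (!all(req %in% names(features))) {
    stop("`features` needs columns pig_id and phase", call. = FALSE)
  }
  missing_params <- setdiff(hypotheses$parameter, names(features))
  if (length(missing_params) > 0L) {
    stop("feature table is missing parameter columns: ",
      paste(missing_params, collapse = ", "),
      call. = FALSE
    )
  }
  bad_dir <- setdiff(hypotheses$direction, c("decrease", "increase"))
  if (length(bad_dir) > 0L) {
    stop("hypothesis directions must be 'decrease' or 'increase'",
      call. = FALSE
    )
  }

  pigs <- sort(unique(as.character(features$pig_id)))
  blocks <- purrr::map(pigs, function(pig) {
    rows <- features[features$pig_id == pig, , drop = FALSE]
    pre <- rows[rows$phase == "pre", , drop = FALSE]
    post <- rows[rows$phase == "post", , drop = FALSE]
    if (nrow(pre) == 0L || nrow(post) == 0L) {
      warning(sprintf(
        "pig '%s' is missing a phase (pre: %d, post: %d squeals); skipped",
        pig, nrow(pre), nrow(post)
      ))
      return(NULL)
    }
    p_raw <- purrr::map2_dbl(
      hypotheses$parameter, hypotheses$direction,
      function(param, dir) {
        wilcoxon_one_sided(pre[[param]], post[[param]], direction = dir)
      }
    )
    adj <- by_fdr(p_raw, alpha = alpha)
    tibble::tibble(
      pig_id = pig,
      parameter = hypotheses$parameter,
      n_pre = nrow(pre),
      n_post = nrow(post),
      direction = hypotheses$direction,
      p_raw = adj$p_raw,
      p_adj = adj$p_adj,
      significant = adj$rejected,
      significance_tier = dplyr::case_when(
        adj$p_adj <= 0.001 ~ "***",
        adj$p_adj <= 0.05 ~ "*",
        TRUE ~ "ns"
      )
    )
  })
  structure(
    list(results = dplyr::bind_rows(blocks), alpha = alpha,
      hypotheses = tibble::as_tibble(hypotheses)
    ),
    class = "squeal_comparison"
  )
}

#' @export
print.squeal_comparison <- function(x, ...) {
  res <- x$results
  cat(sprintf(
    "<squeal_comparison: %d animals x %d parameters, BY FDR at alpha = %g>\n",
    length(unique(res$pig_id)), length(unique(res$parameter)), x$alpha
  ))
  sig <- res[res$significant, c("pig_id", "parameter", "p_adj", "direction")]
  if (nrow(sig) == 0L) {
    cat("No significant pre/post changes after correction.\n")
  } else {
    cat("Significant pre/post changes (BY-adjusted):\n")
    print(as.data.frame(sig), row.names = FALSE)
  }
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a squeal comparison into one row per test
#'
#' @param x A `squeal_comparison` from [compare_phases()].
#' @param ... Unused.
#' @return A tibble with columns `pig_id`, `parameter`, `n_pre`, `n_post`,
#'   `direction`, `p_raw`, `p_adj`, `significant`, `significance_tier`.
#' @method tidy squeal_comparison
#' @export
tidy.squeal_comparison <- function(x, ...) {
  x$results
}

#' One-row summary of a squeal comparison
#'
#' @param x A `squeal_comparison` from [compare_phases()].
#' @param ... Unused.
#' @return A tibble with the number of animals, tests, rejections and the
#'   FDR level.
#' @method glance squeal_comparison
#' @export
glance.squeal_comparison <- function(x, ...) {
  res <- x$results
  tibble::tibble(
    n_pigs = length(unique(res$pig_id)),
    n_tests = nrow(res),
    n_significant = sum(res$significant),
    alpha = x$alpha
  )
}
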