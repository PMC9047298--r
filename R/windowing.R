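#' Define a windowing plan
#'
#' The analysis uses three windowing schemes over one squeal:
#' \describe{
#'   \item{total}{one rectangular window spanning the entire signal —
#'     maximal frequency resolution (PF, Q50, SF_Q50, HNR, RMSI, Dur).}
#'   \item{partial}{eleven evenly spaced, contiguous Hamming windows tiling
#'     the signal; windows 2-10 are the "inner" windows (Q50_2, Q50_10,
#'     Q50_min, Q50_n).}
#'   \item{consecutive}{overlapping fixed-length frames, by default 1024
#'     samples with 50% overlap — short-time parameters that are averaged
#'     (Q50W, Q25, SF) or differenced (Flux).}
#' }
#'
#' @param n_partial Number of partial windows (default 11; minimum 3 so
#'   that inner windows exist).
#' @param frame_len Consecutive frame length in samples (default 1024).
#' @param overlap Fractional overlap between consecutive frames in
#'   `[0, 1)` (default 0.5).
#' @param taper Taper applied to partial and consecutive windows:
#'   `"hamming"` (default) or `"rectangular"`.
#' @return A `window_plan` list.
#' @export
#' @examples
#' window_plan()
#' window_plan(frame_len = 512, overlap = 0.75)
window_plan <- function(n_partial = 11L, frame_len = 1024L, overlap = 0.5,
                        taper = c("hamming", "rectangular")) {
  taper <- match.arg(taper)
  n_partial <- as.integer(n_partial)
  frame_len <- as.integer(frame_len)
  if (n_partial < 3L) stop("`n_partial` must be >= 3", call. = FALSE)
  if (frame_len < 2L) stop("`frame_len` must be >= 2", call. = FALSE)
  if (overlap < 0 || overlap >= 1) {
    stop("`overlap` must be in [0, 1)", call. = FALSE)
  }
  structure(
    list(
      n_partial = n_partial, frame_len = frame_len,
      overlap = overlap, taper = taper
    ),
    class = "window_plan"
  )
}

taper_values <- function(n, taper) {
  if (taper == "hamming") as.numeric(signal::hamming(n)) else rep(1, n)
}

#' Partial windows: eleven evenly spaced Hamming segments
#'
#' Splits the clip into `n_partial` contiguous, non-overlapping segments of
#' equal length `L = floor(N / n_partial)` starting at 0, L, 2L, ...; the
#' trailing `N - n_partial * L` samples are unused. Each segment is
#' multiplied by the plan's taper.
#'
#' @param clip A [squeal_clip()].
#' @param plan A [window_plan()].
#' @return A list of `n_partial` numeric vectors (tapered segments), with
#'   attribute `"starts"` giving the 0-based start sample of each.
#' @export
partial_windows <- function(clip, plan = window_plan()) {
  stopifnot(inherits(clip, "squeal_clip"), inherits(plan, "window_plan"))
  n <- length(clip$samples)
  len <- n %/% plan$n_partial
  if (len < 2L) {
    stop(sprintf(
      "insufficient samples: %d samples cannot support %d partial windows",
      n, plan$n_partial
    ), call. = FALSE)
  }
  w <- taper_values(len, plan$taper)
  starts <- (seq_len(plan$n_partial) - 1L) * len
  out <- lapply(starts, function(s) clip$samples[(s + 1L):(s + len)] * w)
  attr(out, "starts") <- starts
  out
}

#' Consecutive windows: overlapping fixed-length frames
#'
#' Frames of `frame_len` samples start at multiples of
#' `hop = frame_len * (1 - overlap)`; only frames fully inside the signal
#' are produced, so the frame count is `floor((N - frame_len) / hop) + 1`.
#'
#' @inheritParams partial_windows
#' @return A list of tapered frames with attribute `"starts"` (0-based).
#' @export
consecutive_windows <- function(clip, plan = window_plan()) {
  stopifnot(inherits(clip, "squeal_clip"), inherits(plan, "window_plan"))
  n <- length(clip$samples)
  flen <- plan$frame_len
  if (n < flen) {
    stop(sprintf(
      "insufficient samples: clip has %d samples, one frame needs %d",
      n, flen
    ), call. = FALSE)
  }
  hop <- max(1L, as.integer(round(flen * (1 - plan$overlap))))
  n_frames <- (n - flen) %/% hop + 1L
  starts <- (seq_len(n_frames) - 1L) * hop
  w <- taper_values(flen, plan$taper)
  out <- lapply(starts, function(s) clip$samples[(s + 1L):(s + flen)] * w)
  attr(out, "starts") <- starts
  out
}
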