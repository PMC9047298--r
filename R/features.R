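# Internal fast paths: plain numeric vectors, same scaling as
# energy_spectrum()/magnitude_spectrum(), used in per-frame loops.
energy_values <- function(segment) {
  n <- length(segment)
  x <- stats::fft(segment)
  n_bins <- n %/% 2L + 1L
  e <- Mod(x[seq_len(n_bins)])^2 / n
  interior <- seq_len(n_bins) > 1L & !(n %% 2L == 0L & seq_len(n_bins) == n_bins)
  e[interior] <- 2 * e[interior]
  e
}

magnitude_values <- function(segment) {
  n <- length(segment)
  n_bins <- n %/% 2L + 1L
  Mod(stats::fft(segment)[seq_len(n_bins)])
}

bin_freqs <- function(n, sample_rate) {
  (seq_len(n %/% 2L + 1L) - 1L) * sample_rate / n
}

quantile_from_values <- function(values, freqs, q) {
  total <- sum(values)
  if (total <= 0) {
    stop("degenerate spectrum: total energy is zero", call. = FALSE)
  }
  freqs[which(cumsum(values) >= q * total)[1L]]
}

flatness_from_values <- function(v) {
  if (sum(v) <= 0) {
    stop("degenerate spectrum: all values are zero", call. = FALSE)
  }
  if (any(v == 0)) return(0)
  if (all(v == v[1L])) return(1)
  exp(mean(log(v))) / mean(v)
}

#' Root-mean-square intensity of a normalized clip
#'
#' Because clips are peak-normalized, RMSI is a relative loudness/structure
#' measure in (0, 1]: a signal dominated by a few sharp peaks has low RMSI,
#' a dense, saturated signal approaches 1.
#'
#' @param clip A [squeal_clip()].
#' @return `sqrt(mean(samples^2))`, in (0, 1] for a peak-normalized clip.
#' @export
rmsi <- function(clip) {
  stopifnot(inherits(clip, "squeal_clip"))
  if (length(clip$samples) == 0L) stop("empty clip", call. = FALSE)
  sqrt(mean(clip$samples^2))
}

#' Partial-window Q50 parameters
#'
#' Computes Q50 per partial Hamming window (see [partial_windows()]) and
#' summarizes the nine inner windows (1-based indices 2-10 of 11):
#' \describe{
#'   \item{Q50_2}{Q50 of the second window.}
#'   \item{Q50_10}{Q50 of the second-to-last window.}
#'   \item{Q50_min}{lowest inner-window Q50.}
#'   \item{Q50_n}{1-based index of the extreme inner-window Q50 (the
#'     maximum for `q50n_mode = "max"`, the default; ties go to the lowest
#'     index). Always an integer in 2..10.}
#' }
#'
#' @param clip A [squeal_clip()].
#' @param plan A [window_plan()].
#' @param q50n_mode Whether `Q50_n` marks the window with the highest
#'   (`"max"`, default) or lowest (`"min"`) inner-window Q50. The two
#'   readings describe where high harmonics are most vs. least dominant;
#'   both are kept because the parameter's verbal and operational
#'   definitions differ in the literature.
#' @return A one-row tibble with columns `Q50_2`, `Q50_10`, `Q50_min`,
#'   `Q50_n`.
#' @export
q50_partials <- function(clip, plan = window_plan(),
                         q50n_mode = c("max", "min")) {
  q50n_mode <- match.arg(q50n_mode)
  segs <- partial_windows(clip, plan)
  freqs <- bin_freqs(length(segs[[1L]]), clip$sample_rate)
  q50s <- vapply(
    segs,
    function(s) quantile_from_values(energy_values(s), freqs, 0.5),
    numeric(1L)
  )
  inner <- 2:(plan$n_partial - 1L)
  inner_q <- q50s[inner]
  pick <- if (q50n_mode == "max") which.max(inner_q) else which.min(inner_q)
  tibble::tibble(
    Q50_2 = q50s[2L],
    Q50_10 = q50s[plan$n_partial - 1L],
    Q50_min = min(inner_q),
    Q50_n = inner[pick]
  )
}

#' Windowed median frequency Q50W
#'
#' Averages the per-frame energy spectra of the consecutive windows
#' bin-wise and returns the 50% energy quantile of the averaged spectrum.
#'
#' @inheritParams q50_partials
#' @return Frequency in Hz.
#' @export
q50w <- function(clip, plan = window_plan()) {
  frames <- consecutive_windows(clip, plan)
  freqs <- bin_freqs(plan$frame_len, clip$sample_rate)
  e <- vapply(frames, energy_values, numeric(length(freqs)))
  quantile_from_values(rowMeans(e), freqs, 0.5)
}

#' Frame-averaged 25% energy quantile Q25
#'
#' Q25 is computed per consecutive frame and the per-frame values are
#' arithmetically averaged.
#'
#' @inheritParams q50_partials
#' @return Frequency in Hz.
#' @export
q25_mean <- function(clip, plan = window_plan()) {
  frames <- consecutive_windows(clip, plan)
  freqs <- bin_freqs(plan$frame_len, clip$sample_rate)
  mean(vapply(
    frames,
    function(f) quantile_from_values(energy_values(f), freqs, 0.25),
    numeric(1L)
  ))
}

#' Frame-averaged spectral flatness SF
#'
#' @inheritParams q50_partials
#' @return Dimensionless value in `[0, 1]`.
#' @export
sf_mean <- function(clip, plan = window_plan()) {
  frames <- consecutive_windows(clip, plan)
  mean(vapply(
    frames,
    function(f) flatness_from_values(energy_values(f)),
    numeric(1L)
  ))
}

#' Q50-scaled whole-signal spectral flatness SF_Q50
#'
#' Spectral flatness of the total-signal (rectangular-window) energy
#' spectrum divided by the total-signal Q50; units 1/Hz.
#'
#' @param clip A [squeal_clip()].
#' @return Value in 1/Hz.
#' @export
sf_q50 <- function(clip) {
  stopifnot(inherits(clip, "squeal_clip"))
  e <- energy_values(clip$samples)
  freqs <- bin_freqs(length(clip$samples), clip$sample_rate)
  flatness_from_values(e) / quantile_from_values(e, freqs, 0.5)
}

#' Harmonics-to-noise ratio (autocorrelation harmonicity)
#'
#' Frame-wise normalized-autocorrelation harmonicity. For each analysis
#' frame (two pitch-floor periods long, 50% hop, mean-removed) the
#' normalized cross-correlation between the frame and its lagged copy is
#' maximized over lags corresponding to pitch candidates between
#' `floor_pitch` and 1000 Hz, giving the periodic energy fraction
#' `r` in (0, 1). Per-frame harmonicity is `10 * log10(r / (1 - r))` and
#' HNR is the mean over frames.
#'
#' This is a self-contained harmonicity measure for aperiodic animal voice:
#' it agrees qualitatively with classical voice-analysis HNR (strongly
#' periodic signals score high, noise scores low) but is not a clone of any
#' particular tool's algorithm.
#'
#' @param clip A [squeal_clip()].
#' @param floor_pitch Lowest pitch candidate in Hz (default 75).
#' @return HNR in dB.
#' @export
hnr <- function(clip, floor_pitch = 75) {
  stopifnot(inherits(clip, "squeal_clip"))
  fs <- clip$sample_rate
  lag_min <- max(1L, as.integer(ceiling(fs / 1000)))
  lag_max <- as.integer(floor(fs / floor_pitch))
  if (lag_max <= lag_min) {
    stop("sample rate too low for the requested pitch range", call. = FALSE)
  }
  flen <- 2L * lag_max
  hop <- flen %/% 2L
  n <- length(clip$samples)
  if (n < flen + hop) {
    stop(sprintf(
      "clip too short for HNR: need >= %d samples (2 frames at %g Hz floor pitch), got %d",
      flen + hop, floor_pitch, n
    ), call. = FALSE)
  }
  starts <- seq(0L, n - flen, by = hop)
  lags <- lag_min:lag_max
  h <- vapply(starts, function(s) {
    x <- clip$samples[(s + 1L):(s + flen)]
    x <- x - mean(x)
    r <- max(normalized_xcorr(x, lags))
    r <- min(max(r, 1e-12), 1 - 1e-12)
    10 * log10(r / (1 - r))
  }, numeric(1L))
  mean(h)
}

# Normalized cross-correlation of x with its lagged copy at each lag:
# ac(L) / sqrt(e1(L) * e2(L)) with ac from the FFT autocorrelation and the
# segment energies from cumulative sums. O(N log N) per frame.
normalized_xcorr <- function(x, lags) {
  n <- length(x)
  nfft <- stats::nextn(2L * n, 2L)
  X <- stats::fft(c(x, numeric(nfft - n)))
  ac <- Re(stats::fft(X * Conj(X), inverse = TRUE)) / nfft
  cs <- cumsum(x^2)
  total <- cs[n]
  e1 <- cs[n - lags] # energy of x[1:(n-L)]
  e2 <- total - cs[lags] # energy of x[(L+1):n]
  denom <- sqrt(e1 * e2)
  out <- ac[lags + 1L] / denom
  out[denom == 0] <- 0
  out
}

#' Cepstral peak prominence (CPP)
#'
#' Prominence of the dominant peak of the real cepstrum of the dB
#' log-magnitude spectrum of the entire clip, measured above a linear
#' regression trend fitted over the searched quefrency range
#' (1/1000 s to 1/60 s, i.e. pitch candidates 60-1000 Hz). A strongly
#' periodic signal shows a tall, narrow cepstral peak; noise does not.
#' Amplitude scaling shifts the log spectrum by a constant, which only
#' affects the zero-quefrency bin, so CPP is amplitude-invariant.
#'
#' CPP is provided for descriptive comparison only; like other
#' fundamental-frequency-dependent measures it is unreliable on largely
#' aperiodic voice and is excluded from the statistical pipeline.
#'
#' @param clip A [squeal_clip()].
#' @return CPP in dB.
#' @export
cpp <- function(clip) {
  stopifnot(inherits(clip, "squeal_clip"))
  x <- clip$samples
  n <- length(x)
  mag <- Mod(stats::fft(x))
  if (max(mag) == 0) stop("degenerate spectrum", call. = FALSE)
  log_mag_db <- 20 * log10(pmax(mag, .Machine$double.eps))
  ceps <- Re(stats::fft(log_mag_db, inverse = TRUE)) / n
  fs <- clip$sample_rate
  q_idx <- seq_len(n %/% 2L + 1L) # quefrency (i-1)/fs seconds
  quef <- (q_idx - 1L) / fs
  in_range <- which(quef >= 1 / 1000 & quef <= 1 / 60)
  if (length(in_range) < 3L) {
    stop("clip too short for cepstral analysis", call. = FALSE)
  }
  cq <- ceps[in_range]
  peak_i <- which.max(cq)
  trend <- stats::lm.fit(cbind(1, quef[in_range]), cq)$coefficients
  cq[peak_i] - (trend[1L] + trend[2L] * quef[in_range][peak_i])
}

#' Compute the full aperiodic parameter vector for one squeal
#'
#' Assembles the fourteen aperiodic voice parameters for a clip:
#' whole-signal parameters (PF, Q50, Dur, RMSI, HNR, SF_Q50), the
#' partial-window family (Q50_2, Q50_10, Q50_min, Q50_n) and the
#' consecutive-window family (Q50W, Q25, SF, Flux). Optionally appends
#' CPP, which stays off the statistical path.
#'
#' @param clip A [squeal_clip()].
#' @param plan A [window_plan()].
#' @param include_cpp Also compute cepstral peak prominence?
#' @param q50n_mode Passed to [q50_partials()].
#' @param flux_reduce Passed to [spectral_flux()].
#' @return A one-row tibble with one column per parameter.
#' @export
#' @examples
#' clip <- generate_squeal(squeal_model(duration_s = 0.4, seed = 1))
#' squeal_parameters(clip)
squeal_parameters <- function(clip, plan = window_plan(),
                              include_cpp = FALSE,
                              q50n_mode = c("max", "min"),
                              flux_reduce = c("mean", "sum")) {
  stopifnot(inherits(clip, "squeal_clip"))
  q50n_mode <- match.arg(q50n_mode)
  flux_reduce <- match.arg(flux_reduce)
  fs <- clip$sample_rate

  with_param <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop(sprintf("parameter %s: %s", name, conditionMessage(e)),
        call. = FALSE
      )
    })
  }

  total_e <- with_param("PF/Q50/SF_Q50", energy_values(clip$samples))
  total_f <- bin_freqs(length(clip$samples), fs)

  frames <- with_param("Q50W/Q25/SF/Flux", consecutive_windows(clip, plan))
  frame_f <- bin_freqs(plan$frame_len, fs)
  frame_e <- vapply(frames, energy_values, numeric(length(frame_f)))

  q50_total <- with_param("Q50", quantile_from_values(total_e, total_f, 0.5))

  flux_val <- if (length(frames) >= 2L) {
    m <- vapply(frames, magnitude_values, numeric(length(frame_f)))
    m <- sweep(m, 2L, colSums(m), "/") * 100
    d <- m[, -1L, drop = FALSE] - m[, -ncol(m), drop = FALSE]
    ps <- colSums(d^2)
    if (flux_reduce == "mean") mean(ps) else sum(ps)
  } else {
    stop("parameter Flux: insufficient frames (need >= 2 consecutive windows)",
      call. = FALSE
    )
  }

  dplyr::bind_cols(
    tibble::tibble(
      PF = with_param("PF", total_f[which.max(total_e)]),
      Q50 = q50_total
    ),
    with_param("Q50 partials", q50_partials(clip, plan, q50n_mode)),
    tibble::tibble(
      Q50W = quantile_from_values(rowMeans(frame_e), frame_f, 0.5),
      Q25 = mean(apply(frame_e, 2L, quantile_from_values, frame_f, 0.25)),
      Dur = clip_duration(clip),
      SF = mean(apply(frame_e, 2L, flatness_from_values)),
      SF_Q50 = with_param("SF_Q50", flatness_from_values(total_e) / q50_total),
      Flux = flux_val,
      RMSI = with_param("RMSI", rmsi(clip)),
      HNR = with_param("HNR", hnr(clip))
    ),
    if (include_cpp) tibble::tibble(CPP = with_param("CPP", cpp(clip)))
  )
}

#' Names of the fourteen statistical parameters
#'
#' The aperiodic parameters entering the statistical comparison, in
#' canonical order. CPP is descriptive only and not listed.
#'
#' @return Character vector of length 14.
#' @export
aperiodic_parameters <- function() {
  c(
    "PF", "Q50", "Q50_2", "Q50_10", "Q50_min", "Q50W", "Q25",
    "Dur", "Q50_n", "SF", "SF_Q50", "Flux", "RMSI", "HNR"
  )
}

#' Extract the feature table for a cohort of squeals
#'
#' Maps [squeal_parameters()] over a cohort tibble (as returned by
#' [generate_cohort()] or assembled by hand), producing one row per squeal
#' with its metadata and the fourteen parameter columns — the tabular
#' layout consumed by [compare_phases()].
#'
#' @param cohort A data frame with a list-column `clip` of [squeal_clip()]
#'   objects; any other columns (e.g. `clip_id`, `pig_id`, `phase`) are
#'   carried through.
#' @inheritParams squeal_parameters
#' @return A tibble: metadata columns followed by parameter columns.
#' @export
extract_features <- function(cohort, plan = window_plan(),
                             include_cpp = FALSE,
                             q50n_mode = c("max", "min"),
                             flux_reduce = c("mean", "sum")) {
  stopifnot(is.data.frame(cohort), "clip" %in% names(cohort))
  q50n_mode <- match.arg(q50n_mode)
  flux_reduce <- match.arg(flux_reduce)
  params <- purrr::map(
    cohort$clip, squeal_parameters,
    plan = plan, include_cpp = include_cpp,
    q50n_mode = q50n_mode, flux_reduce = flux_reduce
  )
  dplyr::bind_cols(
    tibble::as_tibble(cohort[setdiff(names(cohort), "clip")]),
    dplyr::bind_rows(params)
  )
}
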