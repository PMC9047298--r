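#' One-sided energy spectrum of a windowed segment
#'
#' Computes the discrete Fourier transform of the segment (FFT length =
#' segment length, no zero padding) and returns the one-sided energy
#' spectrum. Bin `k` (0-based) maps to frequency `k * fs / N`. Energies are
#' scaled as `|X_k|^2 / N`, with interior bins (neither DC nor Nyquist)
#' doubled so that the spectrum satisfies Parseval's identity exactly:
#' `sum(energy) == sum(segment^2)`. The DC bin is included in all spectral
#' sums.
#'
#' @param segment Numeric vector of (typically tapered) samples,
#'   length >= 2.
#' @param sample_rate Sampling rate in Hz.
#' @return A tibble with columns `frequency` (Hz, strictly increasing from
#'   0 to Nyquist) and `energy` (nonnegative).
#' @export
energy_spectrum <- function(segment, sample_rate) {
  n <- length(segment)
  if (n < 2L) stop("insufficient samples: segment length must be >= 2",
    call. = FALSE
  )
  x <- stats::fft(segment)
  n_bins <- n %/% 2L + 1L
  e <- Mod(x[seq_len(n_bins)])^2 / n
  # double interior bins; Nyquist bin exists only for even n
  interior <- seq_len(n_bins) > 1L & !(n %% 2L == 0L & seq_len(n_bins) == n_bins)
  e[interior] <- 2 * e[interior]
  tibble::tibble(
    frequency = (seq_len(n_bins) - 1L) * sample_rate / n,
    energy = e
  )
}

#' One-sided magnitude spectrum of a windowed segment
#'
#' Raw one-sided DFT magnitudes `|X_k|` (no doubling, no normalization);
#' the spectral-flux computation rescales each frame to percent magnitude,
#' so absolute scaling is immaterial there.
#'
#' @inheritParams energy_spectrum
#' @return A tibble with columns `frequency` and `magnitude`.
#' @export
magnitude_spectrum <- function(segment, sample_rate) {
  n <- length(segment)
  if (n < 2L) stop("insufficient samples: segment length must be >= 2",
    call. = FALSE
  )
  x <- stats::fft(segment)
  n_bins <- n %/% 2L + 1L
  tibble::tibble(
    frequency = (seq_len(n_bins) - 1L) * sample_rate / n,
    magnitude = Mod(x[seq_len(n_bins)])
  )
}

spectrum_values <- function(spec) {
  # second column of a spectrum tibble (energy or magnitude)
  v <- spec[[2L]]
  if (any(v < 0)) stop("spectrum values must be nonnegative", call. = FALSE)
  v
}

#' Spectral energy quantile
#'
#' The frequency that divides the spectrum's total energy into proportions
#' `q : (1 - q)`: the smallest bin frequency at which the cumulative energy
#' (from 0 Hz upward, DC included) reaches at least `q` times the total.
#' No interpolation between bins is performed — the result is always a bin
#' frequency, matching the parameter's definition as a dividing frequency.
#' `q = 0.5` gives the median frequency Q50; `q = 0.25` gives Q25.
#'
#' @param spec A spectrum tibble from [energy_spectrum()].
#' @param q Quantile fraction in (0, 1).
#' @return Frequency in Hz.
#' @export
spectral_quantile <- function(spec, q) {
  if (!is.numeric(q) || length(q) != 1L || q <= 0 || q >= 1) {
    stop("`q` must be a single fraction in (0, 1)", call. = FALSE)
  }
  v <- spectrum_values(spec)
  total <- sum(v)
  if (total <= 0) {
    stop("degenerate spectrum: total energy is zero", call. = FALSE)
  }
  k <- which(cumsum(v) >= q * total)[1L]
  spec$frequency[k]
}

#' Peak frequency of a spectrum
#'
#' Frequency of the maximum-energy bin; ties are broken toward the lowest
#' frequency.
#'
#' @inheritParams spectral_quantile
#' @return Frequency in Hz.
#' @export
peak_frequency <- function(spec) {
  v <- spectrum_values(spec)
  if (sum(v) <= 0) {
    stop("degenerate spectrum: total energy is zero", call. = FALSE)
  }
  spec$frequency[which.max(v)]
}

#' Spectral flatness
#'
#' The ratio of the geometric to the arithmetic mean of the spectral energy
#' values: 1 for a perfectly flat (white-noise-like) spectrum, approaching
#' 0 for a pure tone. Any zero bin makes the geometric mean — and hence the
#' flatness — exactly 0; no flooring is applied.
#'
#' @inheritParams spectral_quantile
#' @return Dimensionless value in `[0, 1]`.
#' @export
spectral_flatness <- function(spec) {
  v <- spectrum_values(spec)
  if (sum(v) <= 0) {
    stop("degenerate spectrum: all values are zero", call. = FALSE)
  }
  if (any(v == 0)) return(0)
  if (all(v == v[1L])) return(1) # geometric mean of a constant is exact
  exp(mean(log(v))) / mean(v)
}

#' Spectral flux over consecutive frames
#'
#' Measures the time-instability of the spectrum. Each frame's values are
#' first rescaled to sum to 100 (percent magnitude), making the measure
#' invariant to per-frame amplitude. For each pair of neighboring frames
#' the squared differences are summed over all frequency bins; these
#' per-pair sums are then averaged over all pairs (`reduce = "mean"`, the
#' default) or summed (`reduce = "sum"`).
#'
#' @param spectra A list of at least two spectrum tibbles on identical
#'   frequency grids (e.g. [magnitude_spectrum()] of the frames from
#'   [consecutive_windows()]).
#' @param reduce How to combine the per-pair sums over time.
#' @return Nonnegative dimensionless value; 0 iff all normalized frames
#'   are identical.
#' @export
spectral_flux <- function(spectra, reduce = c("mean", "sum")) {
  reduce <- match.arg(reduce)
  if (!is.list(spectra) || length(spectra) < 2L) {
    stop("insufficient frames: spectral flux needs at least 2 spectra",
      call. = FALSE
    )
  }
  freqs <- spectra[[1L]]$frequency
  mat <- vapply(spectra, function(s) {
    if (!isTRUE(all.equal(s$frequency, freqs))) {
      stop("all spectra must share one frequency grid", call. = FALSE)
    }
    v <- spectrum_values(s)
    tot <- sum(v)
    if (tot <= 0) {
      stop("degenerate frame: spectrum sums to zero, cannot normalize",
        call. = FALSE
      )
    }
    100 * v / tot
  }, numeric(length(freqs)))
  d <- mat[, -1L, drop = FALSE] - mat[, -ncol(mat), drop = FALSE]
  pair_sums <- colSums(d^2)
  if (reduce == "mean") mean(pair_sums) else sum(pair_sums)
}
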