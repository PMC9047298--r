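# Signal fixtures built in code. All durations/frequencies chosen so the
# fixtures are fast (< 1 s of audio) yet long enough for every windowing
# scheme.

fs_default <- 44100

make_tone <- function(freq, duration = 0.5, fs = fs_default, phase = 0,
                      id = "tone") {
  t_idx <- seq_len(round(duration * fs)) - 1L
  squeal_clip(sin(2 * pi * freq * t_idx / fs + phase), fs, id = id)
}

# Tone sitting exactly on bin `bin` of an `n_fft`-point frame grid, so its
# consecutive-frame magnitude spectra are phase-invariant.
make_bin_tone <- function(bin = 23L, n_fft = 1024L, duration = 0.5,
                          fs = fs_default) {
  make_tone(bin * fs / n_fft, duration, fs, phase = 0.3, id = "bin_tone")
}

# Exponential 1-octave chirp from f0 to 2*f0.
make_chirp <- function(f0 = 1000, duration = 0.5, fs = fs_default) {
  n <- round(duration * fs)
  inst_f <- f0 * 2^((seq_len(n) - 1L) / (n - 1L))
  squeal_clip(sin(2 * pi * cumsum(inst_f) / fs), fs, id = "chirp")
}

make_noise <- function(duration = 0.5, fs = fs_default, seed = 99) {
  withr_seed(seed)
  squeal_clip(stats::rnorm(round(duration * fs)), fs, id = "noise")
}

# minimal local set.seed that does not need withr
withr_seed <- function(seed) set.seed(seed)

# Independent brute-force oracle for spectral quantiles: linear scan of the
# cumulative sum, no vectorized shortcuts shared with the implementation.
oracle_quantile <- function(freqs, values, q) {
  total <- sum(values)
  acc <- 0
  for (k in seq_along(values)) {
    acc <- acc + values[k]
    if (acc >= q * total) {
      return(freqs[k])
    }
  }
  stop("oracle: quantile not reached")
}

# Exact one-sided rank-sum p-value by enumerating every assignment of the
# pooled ranks to the post group. H1 "post shifted up" uses the upper tail
# of the post rank sum; "post shifted down" the lower tail.
oracle_wilcoxon <- function(x_pre, y_post, direction) {
  pooled <- c(x_pre, y_post)
  stopifnot(!anyDuplicated(pooled))
  ranks <- rank(pooled)
  n_post <- length(y_post)
  obs <- sum(ranks[(length(x_pre) + 1L):length(pooled)])
  combos <- utils::combn(length(pooled), n_post)
  sums <- colSums(matrix(ranks[combos], nrow = n_post))
  if (direction == "increase") mean(sums >= obs) else mean(sums <= obs)
}

# Hand-applied Benjamini-Yekutieli step-up: adjusted p-values
# min_{j >= i} m * c(m) * p_(j) / j, capped at 1, mapped back to input order.
oracle_by_adjust <- function(p) {
  m <- length(p)
  cm <- sum(1 / seq_len(m))
  ord <- order(p)
  adj_sorted <- numeric(m)
  running <- Inf
  for (i in rev(seq_len(m))) {
    running <- min(running, m * cm * p[ord[i]] / i)
    adj_sorted[i] <- min(1, running)
  }
  out <- numeric(m)
  out[ord] <- adj_sorted
  out
}

# Small cohort used by several test files; cached per session.
tiny_cohort <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cache <<- generate_cohort(
        squeal_model(duration_s = 0.3),
        squeal_model(rolloff_cutoff = 2000, duration_s = 0.3),
        n_pre = 8, n_post = 8, pig_id = "pigA", seed = 2024
      )
    }
    cache
  }
})
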