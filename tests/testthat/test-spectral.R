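test_that("single tones peak at the nearest bin and satisfy Parseval", {
  fs <- 44100
  seg <- sin(2 * pi * 1000 * (0:8191) / fs)
  spec <- energy_spectrum(seg, fs)
  expect_equal(peak_frequency(spec),
    spec$frequency[which.min(abs(spec$frequency - 1000))]
  )
  # Parseval: one-sided energies sum to the time-domain energy
  expect_equal(sum(spec$energy), sum(seg^2), tolerance = 1e-9)

  withr_seed(11)
  for (n in c(64, 65, 1000, 1024)) {
    x <- stats::rnorm(n)
    expect_equal(sum(energy_spectrum(x, fs)$energy), sum(x^2),
      tolerance = 1e-6
    )
  }
})

test_that("all-zero segments give zero spectra; short segments error", {
  spec <- energy_spectrum(numeric(16), 1000)
  expect_true(all(spec$energy == 0))
  expect_error(energy_spectrum(numeric(1), 1000), "insufficient")
  expect_error(spectral_quantile(spec, 0.5), "degenerate")
  expect_error(peak_frequency(spec), "degenerate")
  expect_error(spectral_flatness(spec), "degenerate")
})

test_that("spectral quantile returns the first bin crossing the threshold", {
  spec2 <- tibble::tibble(frequency = c(100, 200), energy = c(1, 1))
  expect_equal(spectral_quantile(spec2, 0.5), 100)

  spec1 <- tibble::tibble(frequency = c(0, 250, 500), energy = c(0, 0, 3))
  for (q in c(0.1, 0.25, 0.5, 0.9)) {
    expect_equal(spectral_quantile(spec1, q), 500)
  }

  flat <- tibble::tibble(frequency = seq(0, 900, by = 100), energy = rep(1, 10))
  expect_equal(spectral_quantile(flat, 0.25), 200) # cumulative 30% >= 25%

  expect_error(spectral_quantile(flat, 0), "fraction")
  expect_error(spectral_quantile(flat, 1), "fraction")
})

test_that("spectral quantile equals the brute-force scan on random spectra", {
  withr_seed(12)
  for (i in 1:50) {
    n <- sample(4:512, 1)
    freqs <- seq(0, by = 10, length.out = n)
    vals <- stats::rexp(n) * stats::rbinom(n, 1, 0.8)
    if (sum(vals) == 0) vals[1] <- 1
    spec <- tibble::tibble(frequency = freqs, energy = vals)
    q <- stats::runif(1, 0.05, 0.95)
    expect_identical(spectral_quantile(spec, q), oracle_quantile(freqs, vals, q))
  }
})

test_that("quantiles are monotone in q and under high-frequency attenuation", {
  withr_seed(13)
  for (i in 1:25) {
    n <- sample(8:256, 1)
    freqs <- seq(0, by = 20, length.out = n)
    vals <- stats::rexp(n)
    spec <- tibble::tibble(frequency = freqs, energy = vals)
    qs <- sort(stats::runif(2, 0.05, 0.95))
    expect_lte(spectral_quantile(spec, qs[1]), spectral_quantile(spec, qs[2]))

    # damping energy above a cutoff never raises the median frequency
    cutoff <- sample(freqs, 1)
    damped <- vals
    damped[freqs > cutoff] <- damped[freqs > cutoff] * stats::runif(1, 0, 0.99)
    spec_d <- tibble::tibble(frequency = freqs, energy = damped)
    expect_lte(spectral_quantile(spec_d, 0.5), spectral_quantile(spec, 0.5))
  }
})

test_that("peak frequency breaks ties toward the lowest frequency", {
  spec <- tibble::tibble(frequency = c(0, 400, 800), energy = c(0.5, 2, 2))
  expect_equal(peak_frequency(spec), 400)

  withr_seed(14)
  dominant <- tibble::tibble(
    frequency = c(500, 3000), energy = c(1, 0.5)^2
  )
  expect_equal(peak_frequency(dominant), 500)
  # brute-force argmax agreement
  for (i in 1:20) {
    vals <- stats::rexp(30)
    spec <- tibble::tibble(frequency = 0:29 * 50, energy = vals)
    expect_equal(peak_frequency(spec), (which(vals == max(vals))[1] - 1) * 50)
  }
})

test_that("spectral flatness matches its closed forms and log-domain oracle", {
  flat <- tibble::tibble(frequency = 0:9 * 100, energy = rep(3.7, 10))
  expect_identical(spectral_flatness(flat), 1)

  single <- tibble::tibble(frequency = 0:9 * 100, energy = c(rep(0, 9), 5))
  expect_identical(spectral_flatness(single), 0)

  withr_seed(15)
  for (i in 1:20) {
    v <- stats::rexp(40) + 1e-8
    spec <- tibble::tibble(frequency = 0:39 * 10, energy = v)
    expect_equal(spectral_flatness(spec), exp(mean(log(v))) / mean(v))
    # invariance to uniform scaling
    spec2 <- tibble::tibble(frequency = 0:39 * 10, energy = 7.3 * v)
    expect_equal(spectral_flatness(spec2), spectral_flatness(spec),
      tolerance = 1e-12
    )
  }
})

test_that("spectral flux: closed-form cases and invariances", {
  f <- tibble::tibble(frequency = c(0, 100), magnitude = c(2, 2))
  expect_identical(spectral_flux(list(f, f, f)), 0)

  a <- tibble::tibble(frequency = c(0, 100), magnitude = c(1, 0))
  b <- tibble::tibble(frequency = c(0, 100), magnitude = c(0, 5))
  # normalized to (100, 0) and (0, 100): flux = 100^2 + 100^2
  expect_equal(spectral_flux(list(a, b)), 20000)
  expect_equal(spectral_flux(list(a, b), reduce = "sum"), 20000)
  # three frames, mean vs sum reduction
  expect_equal(spectral_flux(list(a, b, a)), 20000)
  expect_equal(spectral_flux(list(a, b, a), reduce = "sum"), 40000)

  # invariance to per-frame amplitude scaling of raw frames
  withr_seed(16)
  frames <- lapply(1:4, function(i) {
    tibble::tibble(frequency = 0:15 * 100, magnitude = stats::rexp(16))
  })
  scaled <- lapply(frames, function(s) {
    s$magnitude <- s$magnitude * stats::runif(1, 0.1, 10)
    s
  })
  expect_equal(spectral_flux(scaled), spectral_flux(frames), tolerance = 1e-9)
  expect_gte(spectral_flux(frames), 0)

  expect_error(spectral_flux(list(a)), "insufficient")
  zero <- tibble::tibble(frequency = c(0, 100), magnitude = c(0, 0))
  expect_error(spectral_flux(list(a, zero)), "degenerate")
})

test_that("a stationary tone has vanishing flux next to a swept tone", {
  plan <- window_plan()
  tone <- make_bin_tone(duration = 0.4)
  chirp <- make_chirp(1000, duration = 0.4)
  flux_of <- function(clip) {
    frames <- consecutive_windows(clip, plan)
    spectral_flux(lapply(frames, magnitude_spectrum, sample_rate = clip$sample_rate))
  }
  expect_lt(flux_of(tone), 1e-6 * flux_of(chirp))
})
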