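test_that("duration and RMSI match their closed forms", {
  clip <- squeal_clip(rep(c(1, -1), 11025), 44100)
  expect_equal(clip_duration(clip), 0.5)
  expect_equal(rmsi(clip), 1)

  sine <- make_tone(1000, duration = 1.0)
  expect_equal(clip_duration(sine), 1.0)
  expect_equal(rmsi(sine), 1 / sqrt(2), tolerance = 0.001)

  expect_error(squeal_clip(numeric(0), 44100), "at least one")
})

test_that("partial-window Q50 family: stationarity, tie rule, chirp ordering", {
  tone <- make_tone(2000, duration = 0.3)
  qp <- q50_partials(tone)
  expect_equal(qp$Q50_min, qp$Q50_2)
  expect_equal(qp$Q50_min, qp$Q50_10)
  expect_identical(qp$Q50_n, 2L) # all inner windows tie; lowest index wins

  chirp <- make_chirp(500, duration = 0.4) # rising 500 -> 1000 Hz
  qc <- q50_partials(chirp)
  expect_gt(qc$Q50_10, qc$Q50_2)
  expect_identical(qc$Q50_n, 10L)

  # window-wise oracle: recompute window 2's Q50 from scratch
  segs <- partial_windows(chirp, window_plan())
  freqs <- seq(0, by = chirp$sample_rate / length(segs[[2]]),
    length.out = length(segs[[2]]) %/% 2 + 1
  )
  spec2 <- energy_spectrum(segs[[2]], chirp$sample_rate)
  expect_equal(qc$Q50_2, spectral_quantile(spec2, 0.5))

  # min/max switch records the definitional ambiguity
  qmin <- q50_partials(chirp, q50n_mode = "min")
  expect_identical(qmin$Q50_n, 2L)
})

test_that("Q50W and Q25 reduce to single-window values and match oracles", {
  tone <- make_bin_tone(bin = 46, duration = 0.4) # 1981 Hz, on-grid
  plan <- window_plan()
  expect_equal(q50w(tone, plan), 46 * tone$sample_rate / 1024)
  expect_equal(q25_mean(tone, plan), 46 * tone$sample_rate / 1024)

  # single frame: Q50W equals the Q50 of that frame
  short <- squeal_clip(make_noise(0.1)$samples[1:1024], 44100)
  frame <- consecutive_windows(short, plan)[[1]]
  spec <- energy_spectrum(frame, 44100)
  expect_equal(q50w(short, plan), spectral_quantile(spec, 0.5))
  expect_equal(q25_mean(short, plan), spectral_quantile(spec, 0.25))

  # random clip vs explicit bin-wise mean / per-frame oracle
  clip <- make_noise(0.15, seed = 21)
  frames <- consecutive_windows(clip, plan)
  specs <- lapply(frames, energy_spectrum, sample_rate = 44100)
  mean_spec <- tibble::tibble(
    frequency = specs[[1]]$frequency,
    energy = rowMeans(vapply(specs, `[[`, numeric(513), "energy"))
  )
  expect_equal(q50w(clip, plan), spectral_quantile(mean_spec, 0.5))
  expect_equal(
    q25_mean(clip, plan),
    mean(vapply(specs, spectral_quantile, numeric(1), q = 0.25))
  )
})

test_that("spectral flatness separates noise from tone; SF_Q50 decomposes", {
  noise <- make_noise(0.6, seed = 22) # > 50 consecutive frames
  tone <- make_tone(1500, duration = 0.6)
  expect_gt(sf_mean(noise), 0.5) # chi-squared bin limit exp(-gamma) ~ 0.56
  expect_lt(sf_mean(tone), 0.1)
  expect_gt(sf_mean(noise), 5 * sf_mean(tone))

  # definitional decomposition of SF_Q50
  e <- energy_spectrum(tone$samples, tone$sample_rate)
  expect_equal(sf_q50(tone), spectral_flatness(e) / spectral_quantile(e, 0.5))
})

test_that("HNR: tonal signals score high, noise low, amplitude-invariant", {
  sine <- make_tone(1000, duration = 0.4)
  expect_gte(hnr(sine), 25)

  noise <- make_noise(0.4, seed = 23)
  expect_lte(hnr(noise), 5)

  half <- squeal_clip(0.5 * sine$samples, sine$sample_rate, normalize = FALSE)
  expect_equal(hnr(half), hnr(sine), tolerance = 1e-8)

  expect_error(hnr(squeal_clip(rnorm(500), 44100)), "too short")
})

test_that("CPP is higher for a harmonic stack than noise, amplitude-invariant", {
  stack <- generate_squeal(
    squeal_model(f0_start = 300, f0_end = 300, noise_snr_db = 40,
      duration_s = 0.4, seed = 31
    )
  )
  noise <- make_noise(0.4, seed = 32)
  expect_gt(cpp(stack), cpp(noise))
  expect_lt(abs(cpp(noise)), 2) # near the regression trend

  doubled <- squeal_clip(2 * stack$samples, stack$sample_rate,
    normalize = FALSE
  )
  expect_equal(cpp(doubled), cpp(stack), tolerance = 1e-6)
})

test_that("the parameter vector is deterministic and coherent for a tone", {
  tone <- make_bin_tone(bin = 46, duration = 0.35)
  p1 <- squeal_parameters(tone)
  p2 <- squeal_parameters(tone)
  expect_identical(p1, p2)

  # PF and Q50 at the tone bin on the total-signal grid; Q50W on the
  # frame grid
  n <- length(tone$samples)
  grid_total <- (0:(n %/% 2)) * tone$sample_rate / n
  f_true <- 46 * tone$sample_rate / 1024
  expect_equal(p1$PF, grid_total[which.min(abs(grid_total - f_true))])
  expect_equal(p1$Q50, p1$PF)
  expect_equal(p1$Q50W, f_true)

  expect_named(
    p1,
    c("PF", "Q50", "Q50_2", "Q50_10", "Q50_min", "Q50W", "Q25", "Dur",
      "Q50_n", "SF", "SF_Q50", "Flux", "RMSI", "HNR"),
    ignore.order = TRUE
  )
  expect_true(all(aperiodic_parameters() %in% names(p1)))
  expect_false("CPP" %in% names(p1))
  expect_true("CPP" %in% names(squeal_parameters(tone, include_cpp = TRUE)))
})

test_that("parameter vector invariants hold on random synthetic squeals", {
  withr_seed(41)
  models <- lapply(1:12, function(i) {
    squeal_model(
      f0_start = stats::runif(1, 600, 2000),
      f0_end = stats::runif(1, 600, 2000),
      rolloff_cutoff = stats::runif(1, 1500, 10000),
      noise_snr_db = stats::runif(1, 5, 30),
      duration_s = stats::runif(1, 0.3, 0.6),
      seed = i
    )
  })
  nyquist <- 44100 / 2
  for (m in models) {
    p <- squeal_parameters(generate_squeal(m))
    expect_true(p$Q50_n %in% 2:10)
    expect_lte(p$Q50_min, min(p$Q50_2, p$Q50_10))
    expect_true(p$SF >= 0 && p$SF <= 1)
    expect_gte(p$Flux, 0)
    expect_gt(p$RMSI, 0)
    expect_lte(p$RMSI, 1)
    expect_gt(p$Dur, 0)
    freq_params <- c(p$PF, p$Q50, p$Q50_2, p$Q50_10, p$Q50_min, p$Q50W, p$Q25)
    expect_true(all(freq_params >= 0 & freq_params <= nyquist))
  }
})

test_that("high-frequency attenuation moves Q-parameters down, flux up", {
  pre <- lapply(1:6, function(i) {
    squeal_parameters(generate_squeal(
      squeal_model(duration_s = 0.3, seed = i)
    ))
  })
  post <- lapply(1:6, function(i) {
    squeal_parameters(generate_squeal(
      squeal_model(rolloff_cutoff = 2000, duration_s = 0.3, seed = 100 + i)
    ))
  })
  med <- function(lst, f) stats::median(vapply(lst, `[[`, numeric(1), f))
  for (f in c("Q50", "Q25", "Q50W", "PF")) {
    expect_lte(med(post, f), med(pre, f))
  }
  expect_gte(med(post, "Flux"), med(pre, "Flux"))
})

test_that("extract_features maps over a cohort and keeps metadata", {
  cohort <- tiny_cohort()
  feats <- extract_features(cohort)
  expect_identical(nrow(feats), nrow(cohort))
  expect_true(all(c("clip_id", "pig_id", "phase") %in% names(feats)))
  expect_true(all(aperiodic_parameters() %in% names(feats)))
  expect_false("clip" %in% names(feats))
})
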